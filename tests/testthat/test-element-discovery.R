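random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("a planted element flanked by a unique 12-mer is found exactly", {
  set.seed(101)
  bg <- random_seq(2000)
  tsd <- "ACGTTGCAGGTC"
  insert <- random_seq(150)
  g <- paste0(substr(bg, 1, 900), tsd, insert, tsd, substr(bg, 901, 2000))
  cand <- scan_tsd_candidates(c(g1 = g))
  hit <- cand[cand$tsd_length >= 12, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$tsd_length, 12L)
  expect_equal(hit$element_end - hit$element_start, 150L)
  expect_equal(hit$tsd_sequence, tsd)
  # coordinates are 0-based half-open and mutually consistent
  expect_equal(hit$left_tsd_end, hit$element_start)
  expect_equal(hit$element_end, hit$right_tsd_start)
  expect_equal(substr(g, hit$left_tsd_start + 1, hit$left_tsd_end),
               substr(g, hit$right_tsd_start + 1, hit$right_tsd_end))
})

test_that("repeats below min_tsd do not produce candidates", {
  set.seed(102)
  bg <- random_seq(1200)
  tsd7 <- "ACGTTGC"
  insert <- random_seq(200)
  g <- paste0(substr(bg, 1, 600), tsd7, insert, tsd7, substr(bg, 601, 1200))
  cand <- scan_tsd_candidates(c(g1 = g), min_tsd = 8, max_tsd = 25)
  # none of the reported candidates may involve the planted 7-mer interval
  expect_false(any(cand$element_start == 607 & cand$element_end == 807))
})

test_that("invalid bounds and empty sequences are rejected/empty", {
  expect_error(scan_tsd_candidates(c(a = "ACGT"), min_len = 10, max_len = 5),
               "min_len")
  expect_error(scan_tsd_candidates(c(a = "ACGT"), min_tsd = 9, max_tsd = 8),
               "min_tsd")
  expect_error(as_genome_tbl(c(a = "")), "empty")
  short <- scan_tsd_candidates(c(a = "ACGTACGTACGT"))
  expect_equal(nrow(short), 0L)
})

test_that("windows containing N never match", {
  set.seed(103)
  bg <- random_seq(1000)
  tsd <- "ACGTNCGTAA"  # contains N
  insert <- random_seq(150)
  g <- paste0(substr(bg, 1, 500), tsd, insert, tsd, substr(bg, 501, 1000))
  cand <- scan_tsd_candidates(c(g1 = g), min_tsd = 8, max_tsd = 12)
  expect_false(any(grepl("N", cand$tsd_sequence)))
})

test_that("scanner equals the brute-force enumeration on random sequences", {
  set.seed(104)
  for (i in 1:25) {
    n <- sample(400:1500, 1)
    g <- random_seq(n)
    a <- scan_tsd_candidates(c(x = g), min_len = 50, max_len = 300,
                             min_tsd = 5, max_tsd = 12)
    b <- bf_scan_tsd(g, min_len = 50, max_len = 300, min_tsd = 5, max_tsd = 12)
    expect_equal(as.data.frame(a[, names(b)]), as.data.frame(b),
                 ignore_attr = TRUE)
  }
})

test_that("overlap resolution prefers longer TSDs then longer elements", {
  # two overlapping candidates by nesting: R1 + X + R1 where X itself
  # contains R2 + Y + R2 with a longer TSD; boundary characters are pinned
  # so neither repeat can extend by chance
  set.seed(105)
  bg <- random_seq(1500)
  r1 <- "ACGTACCGGT"         # 10
  r2 <- "TTGACCGTAAGGCATG"   # 16
  y <- paste0("A", random_seq(118), "C")
  x <- paste0("A", random_seq(18), "G", r2, y, r2, "T", random_seq(18), "C")
  g <- paste0(substr(bg, 1, 699), "G", r1, x, r1, "T", substr(bg, 702, 1500))
  cand <- scan_tsd_candidates(c(g1 = g), min_len = 100, max_len = 500,
                              min_tsd = 8, max_tsd = 25)
  # within the planted construct the 16-mer candidate wins and the
  # overlapping 10-mer candidate is dropped
  win <- cand[cand$element_start < 915 & cand$element_end > 699, ]
  expect_true(16L %in% win$tsd_length)
  expect_false(10L %in% win$tsd_length)
})

test_that("candidates never violate interval invariants", {
  set.seed(106)
  for (i in 1:10) {
    g <- random_seq(1500)
    cand <- scan_tsd_candidates(c(x = g), min_len = 50, max_len = 400,
                                min_tsd = 5, max_tsd = 15)
    if (nrow(cand)) {
      expect_true(all(cand$left_tsd_end == cand$element_start))
      expect_true(all(cand$element_end == cand$right_tsd_start))
      expect_true(all(cand$tsd_length ==
                        cand$left_tsd_end - cand$left_tsd_start))
      len <- cand$element_end - cand$element_start
      expect_true(all(len >= 50 & len <= 400))
      left <- substring(g, cand$left_tsd_start + 1, cand$left_tsd_end)
      right <- substring(g, cand$right_tsd_start + 1, cand$right_tsd_end)
      expect_equal(left, right)
      expect_equal(left, cand$tsd_sequence)
    }
  }
})

test_that("identical input yields byte-identical output ordering", {
  set.seed(107)
  g <- random_seq(2000)
  a <- scan_tsd_candidates(c(x = g))
  b <- scan_tsd_candidates(c(x = g))
  expect_identical(a, b)
})

## candidate row overlapping the interval where a construct was planted
planted_candidate <- function(cand, start0, end0) {
  hit <- cand[cand$element_start < end0 & cand$element_end > start0, ]
  expect_equal(nrow(hit), 1L)
  hit
}

test_that("classification annotates verbatim and mutated consensus copies", {
  set.seed(108)
  cons <- random_seq(200)
  lib <- tibble::tibble(family = c("CHR1_syn", "CHR2_syn"),
                        consensus = c(cons, random_seq(180)))
  tsd <- "GATTACCAGGTT"
  bg <- random_seq(1200)
  g <- paste0(substr(bg, 1, 600), tsd, cons, tsd, substr(bg, 601, 1200))
  genomes <- c(g1 = g)
  cand <- planted_candidate(scan_tsd_candidates(genomes), 612, 812)
  ann <- classify_candidates(cand, genomes, lib)
  expect_equal(ann$family, "CHR1_syn")
  expect_gte(ann$identity, 0.99)  # repeat may extend 1 nt into the element
  expect_equal(ann$strand, "+")

  # reverse-complement copy is annotated on the minus strand
  rc_cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  g2 <- paste0(substr(bg, 1, 600), tsd, rc_cons, tsd, substr(bg, 601, 1200))
  cand2 <- planted_candidate(scan_tsd_candidates(c(g1 = g2)), 612, 812)
  ann2 <- classify_candidates(cand2, c(g1 = g2), lib)
  expect_equal(ann2$family, "CHR1_syn")
  expect_equal(ann2$strand, "-")

  # random element against an unrelated library stays unclassified
  g3 <- paste0(substr(bg, 1, 600), tsd, random_seq(200), tsd, substr(bg, 601, 1200))
  cand3 <- planted_candidate(scan_tsd_candidates(c(g1 = g3)), 612, 812)
  ann3 <- classify_candidates(cand3, c(g1 = g3), lib, min_identity = 0.8)
  expect_equal(ann3$family, "unclassified")
})

test_that("observed identity of mutated copies is near the simulated rate", {
  set.seed(109)
  cons <- random_seq(300)
  lib <- tibble::tibble(family = "FAM", consensus = cons)
  ids <- replicate(40, {
    chars <- strsplit(cons, "")[[1]]
    mut <- runif(300) < 0.1
    chars[mut] <- vapply(chars[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    el <- paste(chars, collapse = "")
    tsd <- random_seq(12)
    g <- paste0(random_seq(300), tsd, el, tsd, random_seq(300))
    cand <- scan_tsd_candidates(c(x = g))
    cand <- cand[cand$element_start < 612 & cand$element_end > 312, ][1, ]
    classify_candidates(cand, c(x = g), lib, min_identity = 0.8,
                        min_coverage = 0.8)$identity
  })
  # expected identity 0.9; allow binomial error plus local-alignment clipping
  expect_lt(abs(mean(ids, na.rm = TRUE) - 0.9), 0.03)
})

test_that("locus extraction round-trips the planted element and truncates flanks", {
  set.seed(110)
  pg <- plant_genome(3, background_length = 6000, seed = 110)
  cand <- scan_tsd_candidates(pg$genome)
  reg <- extract_locus_region(pg$genome, cand, flank = 50)
  planted <- pg$truth
  for (i in seq_len(nrow(planted))) {
    j <- which(reg$element_start == planted$element_start[i])
    expect_length(j, 1L)
    expect_equal(unname(reg$element_seq[j]), planted$element_seq[i])
  }
  # flank 0 returns the element exactly with empty flanks
  reg0 <- extract_locus_region(pg$genome, cand[1, ], flank = 0)
  expect_equal(unname(reg0$left_flank), "")
  expect_equal(unname(reg0$right_flank), "")
  # boundary truncation: a candidate near the start gets a short left flank
  g <- paste0("GATTACCAGGTT", "A", random_seq(148, seed = 1), "C",
              "GATTACCAGGTT", "T", random_seq(499))
  cnd <- scan_tsd_candidates(c(edge = g))
  cnd <- cnd[cnd$left_tsd_start == 0, ]
  regE <- extract_locus_region(c(edge = g), cnd, flank = 50)
  expect_equal(unname(nchar(regE$left_flank)), 0L)
  # out-of-range coordinates raise a coordinate error
  bad <- cand[1, ]
  bad$element_end <- bad$right_tsd_end <- 10 * nchar(pg$genome$residues)
  expect_error(extract_locus_region(pg$genome, bad), "outside")
})
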