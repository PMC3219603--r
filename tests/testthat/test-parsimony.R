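test_that("known small cases score correctly", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),O);")
  f1 <- camin_sokal_score(tr, c(A = "1", B = "1", C = "0", D = "0", O = "0"))
  expect_equal(f1$min_changes, 1L)
  expect_true(f1$consistent)
  expect_equal(f1$origin_branches[[1]], c("A", "B"))

  f2 <- camin_sokal_score(tr, c(A = "1", B = "0", C = "1", D = "0", O = "0"))
  expect_equal(f2$min_changes, 2L)
  expect_false(f2$consistent)

  f3 <- camin_sokal_score(tr, c(A = "1", B = "?", C = "0", D = "0", O = "0"))
  expect_equal(f3$min_changes, 1L)
  expect_equal(f3$origin_branches[[1]], c("A", "B"))  # ? absorbed

  f4 <- camin_sokal_score(tr, c(A = "?", B = "?", C = "?", D = "?", O = "?"))
  expect_equal(f4$min_changes, 0L)

  # all ingroup 1, outgroup ?: single origin on the ingroup stem
  f5 <- camin_sokal_score(tr, c(A = "1", B = "1", C = "1", D = "1", O = "?"))
  expect_equal(f5$min_changes, 1L)
  expect_equal(sort(f5$origin_branches[[1]]), c("A", "B", "C", "D"))
})

test_that("scorer equals branch-subset brute force on random trees", {
  set.seed(42)
  for (i in 1:120) {
    ntips <- sample(4:8, 1)
    tips <- LETTERS[seq_len(ntips)]
    tr <- random_rooted_tree(tips)
    ch <- random_character(tips)
    mine <- camin_sokal_score(tr, ch)$min_changes
    oracle <- bf_camin_sokal(tr, ch)
    expect_equal(mine, oracle,
                 info = paste(ape::write.tree(tr), paste(ch, collapse = "")))
  }
})

test_that("scorer agrees with Sankoff parsimony under an irreversible cost matrix", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  # phangorn reads cost[i, j] as the change j -> i: forbid 0 -> 1 reversals
  # by an effectively infinite entry in the transposed position
  cost <- matrix(c(0, 1, 1e6, 0), 2, 2,
                 dimnames = list(c("0", "1"), c("0", "1")))
  for (i in 1:25) {
    tips <- letters[1:6]
    tr <- random_rooted_tree(tips)
    # force the root to 0 by adding an all-0 outgroup below the root
    tr2 <- ape::read.tree(
      text = paste0("(OUT,", sub(";$", "", ape::write.tree(tr)), ");"))
    ch <- random_character(tips, pq = 0)
    full <- c(ch, OUT = "0")
    dat <- phangorn::phyDat(matrix(full[tr2$tip.label], ncol = 1,
                                   dimnames = list(tr2$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    sank <- phangorn::parsimony(tr2, dat, method = "sankoff", cost = cost)
    mine <- camin_sokal_score(tr2, full)$min_changes
    expect_equal(mine, as.integer(sank))
  }
})

test_that("replacing ? with a determinate state never decreases the score", {
  set.seed(44)
  for (i in 1:60) {
    tips <- LETTERS[1:6]
    tr <- random_rooted_tree(tips)
    ch <- random_character(tips, pq = 0.4)
    base <- camin_sokal_score(tr, ch)$min_changes
    qs <- names(ch)[ch == "?"]
    if (!length(qs)) next
    for (fill in c("0", "1")) {
      ch2 <- ch
      ch2[qs[1]] <- fill
      expect_gte(camin_sokal_score(tr, ch2)$min_changes, base)
    }
  }
})

test_that("pairwise compatibility is the laminar condition and matches trees", {
  tips <- c("A", "B", "C", "D", "E")
  mk <- function(ones) setNames(ifelse(tips %in% ones, "1", "0"), tips)
  expect_true(check_compatibility(mk(c("A", "B")), mk(c("A", "B", "C"))))
  expect_false(check_compatibility(mk(c("A", "B")), mk(c("B", "C"))))
  expect_true(check_compatibility(mk(c("A", "B")), mk(c("C", "D"))))

  # oracle: compatible iff some rooted tree scores both characters at 1 change
  set.seed(45)
  topos <- all_rooted_topologies(c("A", "B", "C", "D"))
  tips4 <- c("A", "B", "C", "D")
  mk4 <- function(ones) setNames(ifelse(tips4 %in% ones, "1", "0"), tips4)
  subsets <- Filter(function(s) length(s) >= 1,
                    unlist(lapply(1:3, function(k)
                      combn(tips4, k, simplify = FALSE)), recursive = FALSE))
  for (i in seq_along(subsets)) {
    for (j in seq_len(i)) {
      c1 <- mk4(subsets[[i]]); c2 <- mk4(subsets[[j]])
      fits_some_tree <- any(vapply(topos, function(tr) {
        camin_sokal_score(tr, c1)$min_changes <= 1 &&
          camin_sokal_score(tr, c2)$min_changes <= 1
      }, TRUE))
      expect_equal(check_compatibility(c1, c2), fits_some_tree,
                   info = paste(paste(subsets[[i]], collapse = ""),
                                paste(subsets[[j]], collapse = "")))
    }
  }
})

test_that("perfect phylogeny realises exactly the determinate 1-sets", {
  taxa <- c("A", "B", "C", "D", "E")
  st <- cbind(l1 = c("1", "1", "0", "0", "0"),
              l2 = c("1", "1", "1", "0", "0"),
              l3 = c("1", "0", "0", "0", "0"))
  rownames(st) <- taxa
  res <- build_perfect_phylogeny(st)
  expect_equal(nrow(res$conflicts), 0L)
  expect_true(is_clade(res$tree, c("A", "B")))
  expect_true(is_clade(res$tree, c("A", "B", "C")))

  st2 <- cbind(st, bad = c("0", "1", "1", "0", "0"))
  res2 <- build_perfect_phylogeny(st2)
  expect_null(res2$tree)
  expect_true(all(c("l1", "bad") %in% unlist(res2$conflicts)))
})

test_that("random laminar families are realised as clades", {
  set.seed(46)
  for (i in 1:20) {
    taxa <- LETTERS[1:8]
    # build a random laminar family by recursive splitting
    fam <- list()
    split_set <- function(s) {
      if (length(s) < 2 || runif(1) < 0.3) return()
      k <- sample(seq_len(length(s) - 1), 1)
      parts <- list(s[1:k], s[(k + 1):length(s)])
      for (p in parts) {
        if (length(p) >= 2) fam[[length(fam) + 1L]] <<- p
        split_set(p)
      }
    }
    split_set(sample(taxa))
    if (!length(fam)) next
    st <- vapply(fam, function(s) ifelse(taxa %in% s, "1", "0"),
                 character(8))
    rownames(st) <- taxa
    colnames(st) <- paste0("l", seq_len(ncol(st)))
    res <- build_perfect_phylogeny(st)
    expect_equal(nrow(res$conflicts), 0L)
    for (s in fam) expect_true(is_clade(res$tree, s))
  }
})

test_that("exhaustive and branch-and-bound searches agree on random matrices", {
  set.seed(47)
  for (i in 1:12) {
    taxa <- c(LETTERS[1:6], "OUT")
    st <- matrix(sample(c("0", "1", "?"), 6 * 7, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), 7, 6,
                 dimnames = list(taxa, paste0("l", 1:6)))
    st["OUT", ] <- "0"
    ex <- search_mp_trees(st, outgroup = "OUT", mode = "exhaustive")
    bb <- search_mp_trees(st, outgroup = "OUT", mode = "branch_and_bound")
    expect_equal(bb$score, ex$score)
    expect_setequal(vapply(bb$trees, function(t)
      paste(sort(ape::write.tree(t)), collapse = ""), ""),
      vapply(ex$trees, function(t)
        paste(sort(ape::write.tree(t)), collapse = ""), ""))
  }
})

test_that("compatible matrices yield the perfect phylogeny at minimal score", {
  taxa <- c("A", "B", "C", "D", "E", "OUT")
  st <- cbind(l1 = c("1", "1", "0", "0", "0", "0"),
              l2 = c("1", "1", "1", "0", "0", "0"),
              l3 = c("1", "1", "1", "1", "0", "0"),
              l4 = c("1", "0", "0", "0", "0", "0"))
  rownames(st) <- taxa
  res <- search_mp_trees(st, outgroup = "OUT", mode = "branch_and_bound")
  expect_equal(res$score, 4)  # one origin per distinct non-empty 1-set
  cons <- strict_consensus(res$trees)
  expect_true(is_clade(cons, c("A", "B")))
  expect_true(is_clade(cons, c("A", "B", "C")))
  expect_true(is_clade(cons, c("A", "B", "C", "D")))
})

test_that("a single binary character constrains every MP tree", {
  taxa <- c("A", "B", "C", "D", "OUT")
  st <- cbind(l1 = c("1", "1", "0", "0", "0"))
  rownames(st) <- taxa
  res <- search_mp_trees(st, outgroup = "OUT", mode = "exhaustive")
  expect_true(all(vapply(res$trees, function(t) is_clade(t, c("A", "B")), TRUE)))
})

test_that("heuristic search finds the exact optimum on small matrices", {
  set.seed(48)
  for (i in 1:6) {
    taxa <- c(LETTERS[1:7], "OUT")
    st <- matrix(sample(c("0", "1"), 8 * 8, replace = TRUE), 8, 8,
                 dimnames = list(taxa, paste0("l", 1:8)))
    st["OUT", ] <- "0"
    bb <- search_mp_trees(st, outgroup = "OUT", mode = "branch_and_bound")
    heu <- search_mp_trees(st, outgroup = "OUT", mode = "heuristic",
                           starts = 5, seed = i)
    expect_equal(heu$score, bb$score)
  }
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),((C,D),E));")
  cons <- strict_consensus(list(t1, t2))
  expect_true(is_clade(cons, c("A", "B")))
  expect_false(is_clade(cons, c("D", "E")))
  expect_false(is_clade(cons, c("C", "D")))
  same <- strict_consensus(list(t1, t1))
  expect_equal(sort(vapply(node_tip_sets(same)[6:8], paste, "", collapse = "")),
               sort(vapply(node_tip_sets(t1)[6:8], paste, "", collapse = "")))
  expect_error(strict_consensus(list(t1, ape::read.tree(text = "((A,B),C);"))),
               "leaf set")
  # property: consensus clades are clades of every input
  set.seed(49)
  trees <- lapply(1:4, function(i) random_rooted_tree(LETTERS[1:6]))
  cons2 <- strict_consensus(trees)
  sets <- node_tip_sets(cons2)
  internal <- sets[(length(cons2$tip.label) + 1):length(sets)]
  for (s in internal) {
    if (length(s) < 6) {
      for (t in trees) expect_true(is_clade(t, s))
    }
  }
})

test_that("synapomorphy mapping reproduces the published per-branch counts", {
  tree <- cetacean_insertion_tree()
  inf <- filter_informative(synthetic_survey_matrix())$matrix
  ms <- map_synapomorphies(tree, inf)
  count_for <- function(taxa_set) {
    lbl <- paste(sort(taxa_set), collapse = "|")
    n <- ms$branches$n_loci[ms$branches$clade_label == lbl]
    if (length(n)) n else 0L
  }
  taxa <- cetacean_taxa()
  cet <- setdiff(taxa, "Hippopotamus_amphibius")
  odo <- setdiff(cet, c("Balaenoptera_acutorostrata", "Balaenoptera_omurai"))
  cladeC <- setdiff(odo, "Kogia_sima")
  cladeD <- setdiff(cladeC, "Platanista_gangetica")
  cladeE <- setdiff(cladeD, "Mesoplodon_ginkgodens")
  delphinoidea <- setdiff(cladeE, "Lipotes_vexillifer")
  expect_equal(count_for(cet), 8L)
  expect_equal(count_for(odo), 1L)
  expect_equal(count_for(cladeC), 4L)
  expect_equal(count_for(cladeD), 10L)
  expect_equal(count_for(cladeE), 13L)
  expect_equal(count_for(delphinoidea), 11L)
  expect_equal(count_for(taxa[1:7]), 4L)
  expect_equal(nrow(ms$incongruent), 0L)
})

test_that("inconsistent characters are reported separately", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),O);")
  st <- cbind(good = c(A = "1", B = "1", C = "0", D = "0", O = "0"),
              homo = c(A = "1", B = "0", C = "1", D = "0", O = "0"))
  ms <- map_synapomorphies(tr, st)
  expect_equal(ms$incongruent$locus_id, "homo")
  expect_equal(ms$incongruent$min_changes, 2L)
  expect_equal(ms$branches$loci[[1]], "good")
})
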