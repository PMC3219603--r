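test_that("HPD intervals are the shortest covering windows", {
  expect_error(hpd_interval(1), "2 samples")
  expect_equal(unname(hpd_interval(rep(3.5, 10))), c(3.5, 3.5))
  h <- hpd_interval(1:100, 0.95)
  expect_equal(unname(h[2] - h[1]), 94)  # shortest window of 95 integers
  # skewed sample: HPD must be shorter than the equal-tail interval
  set.seed(1)
  x <- rlnorm(20000, 0, 1)
  h2 <- hpd_interval(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(h2[2] - h2[1], q[2] - q[1])
  # large-sample normal: bounds near +-1.96
  z <- rnorm(1e5)
  hz <- hpd_interval(z)
  expect_lt(abs(hz[1] + 1.96), 0.05)
  expect_lt(abs(hz[2] - 1.96), 0.05)
})

test_that("pruning likelihood matches analytic two-taxon results", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(likelihood(aln, tr), log(0.25))
  # JC at distance d: closed form per site
  d <- 0.25
  tr2 <- ape::read.tree(text = "(a:0.125,b:0.125);")
  p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
  set.seed(2)
  tt <- timetree(ape::read.tree(text = "(a:1,b:1);"), ages = c(0, 0, 1))
  sim <- simulate_flank_alignment(tt, 3000, mu = d / 2, sigma = 0)
  nm <- sum(sim["a", ] == sim["b", ])
  analytic <- nm * log(p_same / 4) + (3000 - nm) * log((1 - p_same) / 12)
  expect_equal(likelihood(sim, tr2), analytic, tolerance = 1e-10)
})

test_that("pruning equals explicit summation over internal states", {
  # brute force: sum over all internal node state assignments
  set.seed(3)
  tr <- ape::rtree(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  aln <- matrix(sample(c("A", "C", "G", "T", "N"), 4 * 30, replace = TRUE),
                4, 30, dimnames = list(tr$tip.label, NULL))
  model <- sub_model("HKY", kappa = 3, pi = c(0.3, 0.2, 0.3, 0.2))
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    sinephylo:::model_pmat(model, tr$edge.length[e]))
  code <- c(A = 1, C = 2, G = 3, T = 4)
  ntip <- 4
  brute_site <- function(obs) {
    nodes <- (ntip + 1):(ntip + tr$Nnode)
    total <- 0
    grid <- expand.grid(rep(list(1:4), tr$Nnode))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v) {
        if (v <= ntip) return(obs[v]) else return(grid[g, v - ntip])
      }
      pr <- model$pi[as.integer(assign_state(ntip + 1))]
      okzero <- FALSE
      for (e in seq_len(nrow(tr$edge))) {
        from <- as.integer(assign_state(tr$edge[e, 1]))
        toobs <- assign_state(tr$edge[e, 2])
        if (is.na(toobs)) {  # ambiguous tip: sum over its states = 1 row sum
          pr <- pr * 1
        } else {
          pr <- pr * P[[e]][from, as.integer(toobs)]
        }
      }
      total <- total + pr
    }
    total
  }
  obs_mat <- matrix(code[aln], 4, 30)
  ll_brute <- sum(log(vapply(seq_len(30), function(s) brute_site(obs_mat[, s]), 0)))
  expect_equal(likelihood(aln, tr, model), ll_brute, tolerance = 1e-8)
})

test_that("likelihood is invariant to leaf order and matches an independent engine", {
  skip_if_not_installed("phangorn")
  set.seed(4)
  tt <- cetacean_timetree()
  aln <- simulate_flank_alignment(tt, 800, mu = 0.003, sigma = 0.2)
  tr <- ape::reorder.phylo(tt, "cladewise")
  tr$edge.length <- sinephylo:::edge_durations(tt) * 0.003
  model <- sub_model("JC")
  base <- likelihood(aln, tr, model)
  perm <- aln[sample(rownames(aln)), ]
  expect_equal(likelihood(perm, tr, model), base)
  expect_equal(base, phangorn::pml(tr, phangorn::phyDat(aln))$logLik,
               tolerance = 1e-6)
  # gamma-rate likelihood agrees with phangorn too
  mg <- sub_model("JC", gamma_shape = 0.5)
  pg <- phangorn::pml(tr, phangorn::phyDat(aln), shape = 0.5, k = 4)
  expect_equal(likelihood(aln, tr, mg), pg$logLik, tolerance = 1e-4)
})

test_that("zero-length alignments warn and return 0", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  aln <- matrix(character(0), 2, 0, dimnames = list(c("a", "b"), NULL))
  expect_warning(ll <- likelihood(aln, tr), "zero-length")
  expect_equal(ll, 0)
})

test_that("AIC model selection recovers the generating model class", {
  set.seed(5)
  tt <- timetree(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"),
                 ages = c(0, 0, 0, 0, 2, 1, 1))
  # JC data: JC or K80 must win, and never GTR+G by a margin over 2
  aln_jc <- simulate_flank_alignment(tt, 4000, mu = 0.05, sigma = 0)
  sel <- select_model(aln_jc, candidates = c("JC", "K80", "HKY", "GTR+G"))
  expect_true(sel$table$model[1] %in% c("JC", "K80"))
  gtr_aic <- sel$table$aic[sel$table$model == "GTR+G"]
  best_aic <- sel$table$aic[1]
  expect_gt(gtr_aic - best_aic, 2)

  # strongly asymmetric GTR data: GTR preferred over JC/K80
  mgtr <- sub_model("GTR", rates = c(0.2, 6, 0.3, 0.4, 8, 1),
                    pi = c(0.4, 0.1, 0.1, 0.4))
  aln_gtr <- simulate_flank_alignment(tt, 4000, mu = 0.08, sigma = 0,
                                      model = mgtr)
  sel2 <- select_model(aln_gtr, candidates = c("JC", "K80", "GTR"))
  expect_equal(sel2$table$model[1], "GTR")
})

test_that("site duplication doubles log-likelihoods and keeps clear rankings", {
  set.seed(6)
  tt <- timetree(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"),
                 ages = c(0, 0, 0, 0, 2, 1, 1))
  aln <- simulate_flank_alignment(tt, 600, mu = 0.05, sigma = 0)
  s1 <- select_model(aln, candidates = c("JC", "K80", "HKY"))
  s2 <- select_model(cbind(aln, aln), candidates = c("JC", "K80", "HKY"))
  j1 <- s1$table[order(s1$table$model), ]
  j2 <- s2$table[order(s2$table$model), ]
  expect_equal(j2$loglik, 2 * j1$loglik, tolerance = 1e-6)
  # the parameter-heavy model earns nothing on JC data, so its rank cannot
  # overtake the simpler models (near-ties among JC/K80 may swap)
  expect_false(s1$table$model[1] == "HKY")
  expect_false(s2$table$model[1] == "HKY")
})

test_that("flank concatenation removes element and gapped columns with full bookkeeping", {
  taxa <- c("A", "B", "C")
  aln1 <- matrix(c("A", "A", "A",
                   "C", "C", "C",
                   "G", "G", "-",
                   "T", "-", "-"), 3, 4,
                 dimnames = list(taxa, NULL))
  l1 <- locus_alignment("L1", aln1,
                        tibble::tibble(seq_id = "A", col_start = 2L, col_end = 2L))
  l2 <- locus_alignment("L2", matrix("G", 2, 3, dimnames = list(c("A", "B"), NULL)),
                        tibble::tibble(seq_id = character(0),
                                       col_start = integer(0), col_end = integer(0)))
  fl <- concatenate_flanks(list(l1, l2), taxa = taxa, gap_threshold = 0.5)
  # L1: column 2 removed (element), column 4 removed (2/3 gaps); L2 intact
  expect_equal(ncol(fl$aln), 2L + 3L)
  expect_equal(fl$removal_log$element_columns_removed, c(1L, 0L))
  expect_equal(fl$removal_log$gapped_columns_removed, c(1L, 0L))
  expect_equal(fl$removal_log$columns_retained, c(2L, 3L))
  # conservation: retained columns sum to the partition spans
  expect_equal(sum(fl$removal_log$columns_retained), ncol(fl$aln))
  expect_equal(fl$partitions$end - fl$partitions$start + 1L,
               fl$removal_log$columns_retained)
  # missing taxon filled with N and logged
  expect_true(all(fl$aln["C", 3:5] == "N"))
  expect_equal(fl$removal_log$taxa_filled[[2]], "C")
})

test_that("an element spanning the whole alignment contributes nothing", {
  l <- locus_alignment("L", matrix("A", 2, 5, dimnames = list(c("A", "B"), NULL)),
                       tibble::tibble(seq_id = "A", col_start = 1L, col_end = 5L))
  fl <- concatenate_flanks(list(l), taxa = c("A", "B"))
  expect_equal(ncol(fl$aln), 0L)
  expect_equal(fl$removal_log$columns_retained, 0L)
})

test_that("calibration mapping validates monophyly, duplicates and order", {
  topo <- cetacean_timetree()
  cal <- cetacean_calibrations()
  bad <- cal
  bad$taxa[[2]] <- c("Hippopotamus_amphibius", "Tursiops_aduncus")
  # that pair's MRCA is the root, duplicating the root calibration
  expect_error(mcmc_date(NULL, topo, bad), "same node")
  nonmono <- cal[1, ]
  nonmono$taxa[[1]] <- c("Tursiops_aduncus", "Tursiops_truncatus",
                         "Kogia_sima")
  nonmono$clade <- "notaclade"
  expect_error(sinephylo:::resolve_calibrations(topo, nonmono), "monophyletic")
  conflict <- cal
  conflict$lower[4] <- 60; conflict$upper[4] <- 70  # descendant older than root
  expect_error(mcmc_date(NULL, topo, conflict), "non-overlapping")
})

test_that("prior-only sampling is reproducible and respects order constraints", {
  topo <- cetacean_timetree()
  cal <- cetacean_calibrations()
  f1 <- mcmc_date(NULL, topo, cal, settings = dating_settings(n_sweeps = 400),
                  seed = 9)
  f2 <- mcmc_date(NULL, topo, cal, settings = dating_settings(n_sweeps = 400),
                  seed = 9)
  expect_identical(f1$trace, f2$trace)
  # every sampled state satisfies parent > child for every edge
  ntip <- length(topo$tip.label)
  ages_cols <- seq_len(topo$Nnode)
  for (i in seq_len(nrow(f1$trace))) {
    ages <- c(numeric(ntip), as.numeric(f1$trace[i, ages_cols]))
    expect_true(all(ages[topo$edge[, 1]] > ages[topo$edge[, 2]]))
  }
})

test_that("posterior concentrates near the truth on strongly clocklike data", {
  topo <- cetacean_timetree()
  cal <- cetacean_calibrations()
  set.seed(12)
  aln <- simulate_flank_alignment(topo, 4000, mu = 0.002, sigma = 0)
  fit <- mcmc_date(aln, topo, cal, model = sub_model("JC"),
                   clock = clock_prior(sigma = 0.05, sample_sigma = FALSE),
                   settings = dating_settings(n_sweeps = 1200, burnin = 0.3),
                   seed = 13)
  s <- node_age(fit, c("Neophocaena_phocaenoides", "Delphinapterus_leucas"))
  expect_lt(abs(s$mean - 11.39), 1.5)
  s2 <- node_age(fit, c("Balaenoptera_acutorostrata", "Kogia_sima"))
  expect_lt(abs(s2$mean - 34.40), 4)
  g <- glance(fit)
  expect_true(g$acceptance > 0.1 && g$acceptance < 0.9)
})

test_that("tidiers return one row per node and one-row glances", {
  topo <- cetacean_timetree()
  fit <- mcmc_date(NULL, topo, cetacean_calibrations(),
                   settings = dating_settings(n_sweeps = 300), seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), topo$Nnode)
  expect_true(all(td$hpd_lower <= td$median & td$median <= td$hpd_upper))
  expect_equal(nrow(glance(fit)), 1L)
})
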