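#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted samples.
#'
#' @param samples Numeric vector (length >= 2).
#' @param mass Probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2L) abort("need at least 2 samples for an HPD interval")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

## effective sample size via the initial-positive-sequence autocorrelation sum
ess <- function(x) {
  n <- length(x)
  if (n < 10L || var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Prior settings for the relaxed molecular clock
#'
#' The clock is uncorrelated lognormal: each branch's rate is `mu` times an
#' independent multiplier drawn from LogNormal(-sigma^2/2, sigma) (mean 1).
#'
#' @param rate_meanlog,rate_sdlog Lognormal prior on the mean rate `mu`
#'   (substitutions/site/Ma). Defaults centre on 0.002, a typical neutral
#'   nuclear mammalian rate.
#' @param sigma Initial (or fixed) log-scale SD of branch rates.
#' @param sample_sigma Sample sigma (exponential prior) or keep it fixed.
#' @param sigma_rate Rate of the exponential prior on sigma.
#' @return A `clock_prior` list.
#' @export
clock_prior <- function(rate_meanlog = log(0.002), rate_sdlog = 0.5,
                        sigma = 0.3, sample_sigma = TRUE,
                        sigma_rate = 1 / 0.3) {
  list(rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog, sigma = sigma,
       sample_sigma = sample_sigma, sigma_rate = sigma_rate)
}

#' MCMC settings for the dating sampler
#'
#' One sweep proposes an update of every node age, every branch-rate
#' multiplier, the mean rate, kappa (when sampled) and sigma.
#'
#' @param n_sweeps Total sweeps.
#' @param sample_every Record every this many post-burn-in sweeps.
#' @param burnin Fraction of sweeps discarded (default 0.1).
#' @param w_age Age sliding-window half-width multiplier (Ma).
#' @param w_mult,w_mu,w_kappa,w_sigma Multiplicative proposal widths.
#' @param w_scale Width of the joint age/rate scaling move.
#' @return A `dating_settings` list.
#' @export
dating_settings <- function(n_sweeps = 4000L, sample_every = 2L, burnin = 0.1,
                            w_age = 4, w_mult = 1.2, w_mu = 0.4,
                            w_kappa = 0.5, w_sigma = 0.8, w_scale = 0.25) {
  list(n_sweeps = as.integer(n_sweeps), sample_every = as.integer(sample_every),
       burnin = burnin, w_age = w_age, w_mult = w_mult, w_mu = w_mu,
       w_kappa = w_kappa, w_sigma = w_sigma, w_scale = w_scale)
}

resolve_calibrations <- function(topology, calibrations) {
  nodes <- integer(nrow(calibrations))
  for (i in seq_len(nrow(calibrations))) {
    taxa <- calibrations$taxa[[i]]
    node <- mrca_node(topology, taxa)
    if (length(taxa) > 2L && !is_clade(topology, taxa)) {
      abort(paste0("calibration '", calibrations$clade[i],
                   "': taxa are not monophyletic in the topology"))
    }
    nodes[i] <- node
  }
  if (anyDuplicated(nodes)) {
    abort("two calibrations map to the same node")
  }
  # hard lower bounds must respect ancestor-descendant order
  ntip <- length(topology$tip.label)
  anc <- function(v) {
    out <- integer(0)
    repeat {
      e <- which(topology$edge[, 2] == v)
      if (!length(e)) break
      v <- topology$edge[e, 1]
      out <- c(out, v)
    }
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      # j ancestral to i: descendant's hard minimum above ancestor's upper
      # bound leaves the priors no common support worth the name
      if (i != j && nodes[j] %in% anc(nodes[i]) &&
          calibrations$lower[i] > calibrations$upper[j]) {
        abort("non-overlapping calibration constraints")
      }
    }
  }
  nodes
}

init_ages <- function(topology, calib_nodes, calib_med) {
  ntip <- length(topology$tip.label)
  nn <- ntip + topology$Nnode
  ages <- numeric(nn)
  po <- ape::reorder.phylo(topology, "postorder")$edge
  for (v in unique(po[, 1])) {  # postorder: children already set
    kids <- po[po[, 1] == v, 2]
    base <- max(ages[kids])
    k <- match(v, calib_nodes)
    target <- if (!is.na(k)) calib_med[k] else base * 1.25 + 2
    ages[v] <- max(target, base + 0.1)
  }
  ages
}

#' Estimate node ages under a fossil-calibrated relaxed clock
#'
#' Metropolis-Hastings sampling of node ages (order constraints enforced),
#' per-branch lognormal rate multipliers, the mean clock rate, kappa (for
#' K80/HKY models) and the clock SD, on a fixed rooted topology. The tree
#' prior is uniform on node ages given the root; calibrated nodes carry
#' lognormal age priors with offset at the younger bound. With `alignment =
#' NULL` the sampler draws from the joint prior.
#'
#' @param alignment Character matrix (taxa x sites), `flank_alignment`, or
#'   `NULL` for prior-only sampling.
#' @param topology Rooted `phylo`; tips must match the alignment taxa.
#' @param calibrations Tibble like [cetacean_calibrations()]: `clade`, `taxa`
#'   (list-column), `lower`, `upper`, `sdlog`.
#' @param model A [sub_model()]; default HKY with empirical frequencies.
#'   Discrete-gamma heterogeneity is not sampled here (see vignette).
#' @param clock A [clock_prior()].
#' @param settings A [dating_settings()].
#' @param seed Integer seed for the sampler.
#' @param init Optional list with `ages` (internal-node ages), `mu`, `sigma`,
#'   `mult` to start from (e.g. a prior draw).
#' @return A `flank_dating` object: trace tibble, per-node age summaries
#'   (mean, median, 95% HPD, ESS), acceptance rate, settings.
#' @export
mcmc_date <- function(alignment, topology, calibrations,
                      model = NULL, clock = clock_prior(),
                      settings = dating_settings(), seed = 1L,
                      init = NULL) {
  topology <- ape::reorder.phylo(topology, "cladewise")
  ntip <- length(topology$tip.label)
  use_lik <- !is.null(alignment)
  if (use_lik) {
    if (inherits(alignment, "flank_alignment")) alignment <- alignment$aln
    if (ncol(alignment) == 0L) use_lik <- FALSE
  }
  if (use_lik && !all(topology$tip.label %in% rownames(alignment))) {
    abort("alignment missing taxa present in the topology")
  }
  if (use_lik && is.null(model)) {
    model <- sub_model("HKY", kappa = 2, pi = empirical_pi(alignment))
  }
  if (!use_lik && is.null(model)) model <- sub_model("JC")
  enc <- if (use_lik) {
    e <- encode_alignment(alignment[topology$tip.label, , drop = FALSE])
    e
  } else {
    list(patterns = matrix(integer(0), ntip, 0), weights = numeric(0))
  }
  nodes <- resolve_calibrations(topology, calibrations)
  cp <- Map(calibration_params, calibrations$lower, calibrations$upper,
            calibrations$sdlog)
  calib_med <- vapply(cp, function(p) p$offset + exp(p$meanlog), 0)
  sample_kappa <- model$type %in% c("K80", "HKY")
  ages0 <- if (!is.null(init)) c(numeric(ntip), init$ages) else
    init_ages(topology, nodes, calib_med)
  nedge <- nrow(topology$edge)
  res <- mcmc_date_cpp(
    edge = topology$edge, ntip = ntip,
    patterns = enc$patterns, weights = enc$weights,
    use_likelihood = use_lik,
    pi = model$pi, gtr_rates = model$rates,
    kappa0 = if (!is.null(init) && !is.null(init$kappa)) init$kappa else model$kappa,
    sample_kappa = sample_kappa,
    kappa_meanlog = log(2), kappa_sdlog = 1,
    ages0 = ages0[(ntip + 1):(ntip + topology$Nnode)],
    mu0 = if (!is.null(init)) init$mu else exp(clock$rate_meanlog),
    sigma0 = if (!is.null(init)) init$sigma else clock$sigma,
    mult0 = if (!is.null(init)) init$mult else rep(1, nedge),
    calib_node = nodes,
    calib_offset = vapply(cp, `[[`, 0, "offset"),
    calib_meanlog = vapply(cp, `[[`, 0, "meanlog"),
    calib_sdlog = vapply(cp, `[[`, 0, "sdlog"),
    mu_meanlog = clock$rate_meanlog, mu_sdlog = clock$rate_sdlog,
    sample_sigma = clock$sample_sigma, sigma_rate = clock$sigma_rate,
    n_sweeps = settings$n_sweeps, sample_every = settings$sample_every,
    burnin_sweeps = as.integer(settings$burnin * settings$n_sweeps),
    w_age_node = settings$w_age *
      pmax(0.5, ages0[(ntip + 1):(ntip + topology$Nnode)] / 10),
    w_mult = settings$w_mult, w_mu = settings$w_mu,
    w_kappa = settings$w_kappa, w_sigma = settings$w_sigma,
    w_scale = settings$w_scale %||% 0.25,
    seed = as.integer(seed))
  samp <- res$samples
  sets <- node_tip_sets(topology)
  node_ids <- (ntip + 1L):(ntip + topology$Nnode)
  labels <- vapply(sets[node_ids], function(s) {
    s <- sort(s)
    if (length(s) == ntip) "root" else
      paste0("mrca_", s[1], "_", s[length(s)], "_n", length(s))
  }, "")
  colnames(samp) <- c(labels, "mu", "sigma", "kappa", "loglik", "logprior")
  trace <- tibble::as_tibble(samp)
  trace$iter <- seq_len(nrow(trace))
  summaries <- purrr::map_dfr(seq_along(node_ids), function(k) {
    x <- samp[, k]
    h <- hpd_interval(x)
    tibble::tibble(node = node_ids[k], label = labels[k],
                   taxa = list(sort(sets[[node_ids[k]]])),
                   n_taxa = length(sets[[node_ids[k]]]),
                   mean = mean(x), median = median(x),
                   hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
                   ess = ess(x))
  })
  out <- list(trace = trace, summaries = summaries,
              acceptance = res$acceptance,
              final_state = list(ages = res$final_ages, mu = res$final_mu,
                                 sigma = res$final_sigma,
                                 kappa = res$final_kappa,
                                 mult = res$final_mult),
              topology = topology, calibrations = calibrations,
              model = model, settings = settings,
              prior_only = !use_lik)
  class(out) <- "flank_dating"
  out
}

#' @export
print.flank_dating <- function(x, ...) {
  cat("Relaxed-clock dating", if (x$prior_only) "(prior-only)", ":",
      nrow(x$trace), "samples, acceptance",
      sprintf("%.2f", x$acceptance), "\n")
  print(x$summaries[, c("label", "mean", "median", "hpd_lower", "hpd_upper")])
  invisible(x)
}

#' @rdname mcmc_date
#' @param x A `flank_dating` object.
#' @param ... Unused.
#' @export
tidy.flank_dating <- function(x, ...) x$summaries

#' @rdname mcmc_date
#' @export
glance.flank_dating <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$trace),
                 acceptance = x$acceptance,
                 ess_logpost = ess(x$trace$loglik + x$trace$logprior),
                 model = x$model$type,
                 prior_only = x$prior_only)
}

#' Posterior age summary of the MRCA of a taxon set
#'
#' @param fit A `flank_dating`.
#' @param taxa Tip labels whose MRCA age is wanted.
#' @return One-row tibble from the fit's summaries.
#' @export
node_age <- function(fit, taxa) {
  node <- mrca_node(fit$topology, taxa)
  fit$summaries[fit$summaries$node == node, ]
}

#' Posterior age samples of the MRCA of a taxon set
#' @inheritParams node_age
#' @return Numeric vector of sampled ages.
#' @export
node_age_samples <- function(fit, taxa) {
  node <- mrca_node(fit$topology, taxa)
  lab <- fit$summaries$label[fit$summaries$node == node]
  fit$trace[[lab]]
}

#' Export a dated tree with posterior mean node ages
#'
#' Builds a `timetree` from the fit's topology and posterior mean ages
#' (branch lengths in Ma) and optionally writes it as Newick.
#'
#' @param fit A `flank_dating`.
#' @param path Optional output path for the Newick string.
#' @return The `timetree` (invisibly when writing).
#' @export
dated_tree <- function(fit, path = NULL) {
  ntip <- length(fit$topology$tip.label)
  ages <- c(numeric(ntip), fit$summaries$mean[order(fit$summaries$node)])
  tt <- timetree(fit$topology, ages = ages)
  if (!is.null(path)) {
    ape::write.tree(tt, path)
    return(invisible(tt))
  }
  tt
}

#' Draw one state from the joint prior of the dating model
#'
#' Runs a prior-only chain and returns its final state; used to initialise
#' samplers and to draw ground truth for coverage simulations.
#'
#' @inheritParams mcmc_date
#' @param n_sweeps Prior-chain length.
#' @return List with `ages` (internal nodes, ape order), `mu`, `sigma`,
#'   `mult`, and `timetree` (the drawn `timetree`).
#' @export
draw_dating_prior <- function(topology, calibrations, clock = clock_prior(),
                              n_sweeps = 600L, seed = 1L) {
  fit <- mcmc_date(NULL, topology, calibrations, clock = clock,
                   settings = dating_settings(n_sweeps = n_sweeps,
                                              sample_every = max(1L, n_sweeps %/% 4L),
                                              burnin = 0),
                   seed = seed)
  ntip <- length(fit$topology$tip.label)
  ages <- c(numeric(ntip), fit$final_state$ages)
  tt <- timetree(fit$topology, ages = ages)
  list(ages = fit$final_state$ages, mu = fit$final_state$mu,
       sigma = fit$final_state$sigma, mult = fit$final_state$mult,
       timetree = tt)
}
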