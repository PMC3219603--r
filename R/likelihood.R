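#' Specify a nucleotide substitution model
#'
#' Reversible models from the nested JC/K80/HKY/GTR family, optionally with
#' discrete-gamma rate heterogeneity (4 categories by default). The rate
#' matrix is scaled to one expected substitution per site per unit branch
#' length.
#'
#' @param type One of `"JC"`, `"K80"`, `"HKY"`, `"GTR"`.
#' @param kappa Transition/transversion rate ratio (K80/HKY).
#' @param rates GTR exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (GT fixed at 1 by convention).
#' @param pi Stationary frequencies (A, C, G, T); equal for JC/K80.
#' @param gamma_shape Discrete-gamma shape, or `NULL` for equal site rates.
#' @param ncat Number of gamma categories.
#' @return A `sub_model` list.
#' @export
sub_model <- function(type = c("JC", "K80", "HKY", "GTR"), kappa = 2,
                      rates = c(1, 1, 1, 1, 1, 1), pi = rep(0.25, 4),
                      gamma_shape = NULL, ncat = 4L) {
  type <- match.arg(type)
  if (type %in% c("JC", "K80")) pi <- rep(0.25, 4)
  rates <- switch(type,
    JC = rep(1, 6),
    K80 = c(1, kappa, 1, 1, kappa, 1),
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  pi <- pi / sum(pi)
  structure(list(type = type, kappa = kappa, rates = rates, pi = pi,
                 gamma_shape = gamma_shape, ncat = as.integer(ncat)),
            class = "sub_model")
}

model_Q <- function(model) {
  r <- model$rates; pi <- model$pi
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  idx <- 1
  for (i in 1:3) for (j in (i + 1):4) {
    Q[i, j] <- r[idx] * pi[j]
    Q[j, i] <- r[idx] * pi[i]
    idx <- idx + 1
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * pi)
}

model_pmat <- function(model, t) {
  Q <- model_Q(model)
  pi <- model$pi
  B <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sqrt(pi)) %*% e$vectors
  Ui <- t(e$vectors) %*% diag(sqrt(pi))
  P <- U %*% diag(exp(e$values * t)) %*% Ui
  pmax(P, 0)
}

#' Discrete-gamma category rates
#'
#' Equal-probability categories, each represented by its conditional mean
#' rate (the standard discretisation for among-site rate heterogeneity).
#'
#' @param shape Gamma shape parameter.
#' @param ncat Number of equal-probability categories.
#' @return Rates normalised to mean 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  q <- qgamma(seq_len(ncat - 1) / ncat, shape = shape, rate = shape)
  bounds <- c(0, q, Inf)
  # E[X | a < X < b] for X ~ Gamma(shape, shape) via the alpha+1 identity
  upper <- stats::pgamma(bounds[-1], shape + 1, rate = shape)
  lower <- stats::pgamma(bounds[-length(bounds)], shape + 1, rate = shape)
  r <- ncat * (upper - lower)
  r / mean(r)
}

## alignment (character matrix taxa x sites) -> compressed site patterns
encode_alignment <- function(aln) {
  codes <- matrix(4L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  map <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  up <- toupper(aln)
  for (b in names(map)) codes[up == b] <- map[[b]]
  if (ncol(codes) == 0L) {
    return(list(patterns = codes, weights = numeric(0)))
  }
  key <- apply(codes, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = codes[, first, drop = FALSE], weights = as.numeric(tab))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Branch lengths are expected substitutions per site; gaps, N and ambiguity
#' codes are treated as fully ambiguous. Under a discrete-gamma model the
#' site likelihood is averaged over equal-probability rate categories.
#'
#' @param alignment Character matrix (taxa x sites) over A/C/G/T/-/N, or a
#'   `flank_alignment`.
#' @param tree Rooted `phylo` with `edge.length` in substitutions/site; tips
#'   must cover the alignment's taxa.
#' @param model A [sub_model()].
#' @return Log-likelihood (numeric scalar). A zero-length alignment returns 0
#'   with a warning.
#' @export
likelihood <- function(alignment, tree, model = sub_model("JC")) {
  if (inherits(alignment, "flank_alignment")) alignment <- alignment$aln
  if (ncol(alignment) == 0L) {
    warn("zero-length alignment: log-likelihood 0 by convention")
    return(0)
  }
  enc <- encode_alignment(alignment)
  rates <- if (is.null(model$gamma_shape)) 1 else
    discrete_gamma_rates(model$gamma_shape, model$ncat)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  eo <- po$edge
  el <- po$edge.length
  tipidx <- match(tree$tip.label, rownames(enc$patterns))
  if (anyNA(tipidx)) abort("alignment is missing tree taxa")
  npat <- ncol(enc$patterns)
  pi <- model$pi
  site_lik <- matrix(0, 1, npat)
  for (r in rates) {
    partial <- vector("list", nn)
    for (i in seq_len(ntip)) {
      x <- enc$patterns[tipidx[i], ]
      m <- matrix(0, 4, npat)
      det <- x < 4L
      m[cbind(x[det] + 1L, which(det))] <- 1
      m[, !det] <- 1
      partial[[i]] <- m
    }
    for (e in seq_len(nrow(eo))) {
      p <- eo[e, 1]; ch <- eo[e, 2]
      P <- model_pmat(model, el[e] * r)
      contrib <- P %*% partial[[ch]]
      partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
    }
    site_lik <- site_lik + (pi %*% partial[[ntip + 1L]]) / length(rates)
  }
  sum(enc$weights * log(as.vector(site_lik)))
}

model_param_count <- function(type, gamma) {
  k <- switch(type, JC = 0L, K80 = 1L, HKY = 4L, GTR = 8L)
  k + as.integer(gamma)
}

empirical_pi <- function(aln) {
  up <- toupper(aln)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(up == b), 0)
  counts / sum(counts)
}

#' Choose a substitution model by AIC
#'
#' Fits each candidate model by maximum likelihood of its substitution
#' parameters on a fixed neighbour-joining tree (topology and branch lengths
#' from JC distances, with a global branch-length scale re-optimised per
#' model) and returns the AIC ranking. AIC = 2k - 2lnL with k the number of
#' free substitution parameters; branch lengths are shared across candidates
#' and drop out of the comparison.
#'
#' @param alignment Character matrix (taxa x sites) or `flank_alignment`.
#' @param candidates Model names from `JC`, `K80`, `HKY`, `GTR`, each
#'   optionally suffixed `+G`.
#' @return List with `best` (fitted [sub_model()]), `table` (tibble: model,
#'   k, loglik, aic, ordered by AIC).
#' @export
select_model <- function(alignment,
                         candidates = c("JC", "K80", "HKY", "GTR",
                                        "JC+G", "K80+G", "HKY+G", "GTR+G")) {
  if (inherits(alignment, "flank_alignment")) alignment <- alignment$aln
  dna <- ape::as.DNAbin(tolower(alignment))
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)], 0.75)
  tree <- ape::nj(d)
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  pi_emp <- empirical_pi(alignment)

  fit_one <- function(name) {
    gamma <- grepl("\\+G$", name)
    type <- sub("\\+G$", "", name)
    # parameters: global branch scale, then substitution parameters
    par0 <- 0; lower <- log(0.02); upper <- log(50)
    if (type %in% c("K80", "HKY")) {
      par0 <- c(par0, log(2)); lower <- c(lower, log(0.05))
      upper <- c(upper, log(100))
    } else if (type == "GTR") {
      par0 <- c(par0, rep(0, 5)); lower <- c(lower, rep(log(0.01), 5))
      upper <- c(upper, rep(log(100), 5))
    }
    if (gamma) {
      par0 <- c(par0, 0); lower <- c(lower, log(0.05)); upper <- c(upper, log(50))
    }
    mk <- function(par) {
      rest <- par[-1]
      i <- 1
      kappa <- 2; rates <- rep(1, 6)
      if (type %in% c("K80", "HKY")) { kappa <- exp(rest[i]); i <- i + 1 }
      if (type == "GTR") { rates <- c(exp(rest[1:5]), 1); i <- 6 }
      shape <- if (gamma) exp(rest[i]) else NULL
      sub_model(type, kappa = kappa, rates = rates,
                pi = if (type %in% c("HKY", "GTR")) pi_emp else rep(0.25, 4),
                gamma_shape = shape)
    }
    negll <- function(par) {
      tr <- tree
      tr$edge.length <- tree$edge.length * exp(par[1])
      -likelihood(alignment, tr, mk(par))
    }
    opt <- tryCatch(
      optim(par0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(opt)) {
      warn(paste("optimisation failed for", name, "- using start values"))
      opt <- list(par = par0, value = negll(par0), convergence = 1L)
    }
    if (opt$convergence != 0L) {
      warn(paste("optimiser did not fully converge for", name))
    }
    k <- model_param_count(type, gamma)
    list(name = name, loglik = -opt$value, k = k,
         aic = 2 * k + 2 * opt$value, model = mk(opt$par))
  }
  fits <- lapply(candidates, fit_one)
  tab <- tibble::tibble(
    model = vapply(fits, `[[`, "", "name"),
    k = vapply(fits, `[[`, 0L, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"))
  ord <- order(tab$aic)
  list(best = fits[[ord[1]]]$model, table = tab[ord, ])
}
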