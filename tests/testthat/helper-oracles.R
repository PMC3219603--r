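## Independent oracles used across tests. These deliberately re-derive the
## quantities from first principles (exhaustive enumeration) rather than
## calling the implementation's machinery.

## O(n^2 k) brute-force TSD scan: enumerate every (left position, repeat
## length, spacing) triple, then the same maximality and overlap-resolution
## rules as the scanner.
bf_scan_tsd <- function(s, min_len = 100L, max_len = 500L,
                        min_tsd = 8L, max_tsd = 25L, resolve = TRUE) {
  n <- nchar(s)
  rows <- list()
  for (k in min_tsd:max_tsd) {
    if (n < 2L * k + min_len) break
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    valid <- !grepl("[^ACGT]", kmers)
    for (d in (k + min_len):(k + max_len)) {
      iidx <- seq_len(max(0L, n - k + 1L - d))
      if (!length(iidx)) break
      hit <- valid[iidx] & valid[iidx + d] & kmers[iidx] == kmers[iidx + d]
      for (i in iidx[hit]) {
        rows[[length(rows) + 1L]] <- c(i = i, j = i + d, k = k)
      }
    }
  }
  if (!length(rows)) return(sinephylo:::empty_candidates())
  m <- do.call(rbind, rows)
  cand <- tibble::tibble(
    left_tsd_start = m[, "i"] - 1L,
    left_tsd_end = m[, "i"] - 1L + m[, "k"],
    element_start = m[, "i"] - 1L + m[, "k"],
    element_end = m[, "j"] - 1L,
    right_tsd_start = m[, "j"] - 1L,
    right_tsd_end = m[, "j"] - 1L + m[, "k"],
    tsd_length = m[, "k"])
  cand <- dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(cand, element_start, element_end),
    tsd_length, n = 1L, with_ties = FALSE))
  if (resolve) cand <- sinephylo:::resolve_tsd_overlaps(cand)
  dplyr::arrange(cand, element_start, element_end - element_start)
}

## Brute-force Camin-Sokal: minimum over all subsets of edges receiving a
## 0 -> 1 change such that implied tip states match every determinate state
## (a tip is 1 iff some edge on its root path changed; root state 0).
bf_camin_sokal <- function(tree, character) {
  st <- suppressWarnings(as.integer(character))
  names(st) <- names(character)
  st[character == "?"] <- NA
  ntip <- length(tree$tip.label)
  E <- nrow(tree$edge)
  # tip x edge root-path incidence
  P <- matrix(FALSE, ntip, E)
  for (t in seq_len(ntip)) {
    v <- t
    repeat {
      e <- which(tree$edge[, 2] == v)
      if (!length(e)) break
      P[t, e] <- TRUE
      v <- tree$edge[e, 1]
    }
  }
  obs <- st[tree$tip.label]
  ones <- which(!is.na(obs) & obs == 1L)
  zeros <- which(!is.na(obs) & obs == 0L)
  if (!length(ones)) return(0L)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), E)))
  implied <- P %*% t(subsets) > 0            # ntip x 2^E
  ok <- rep(TRUE, ncol(implied))
  if (length(ones)) {
    ok <- ok & colSums(implied[ones, , drop = FALSE]) == length(ones)
  }
  if (length(zeros)) {
    ok <- ok & colSums(implied[zeros, , drop = FALSE]) == 0L
  }
  min(rowSums(subsets)[ok])
}

## random rooted binary tree on given tips
random_rooted_tree <- function(tips) {
  tr <- ape::rtree(length(tips), rooted = TRUE, tip.label = sample(tips))
  tr$edge.length <- NULL
  tr
}

## random character over {0,1,?} with controllable missingness
random_character <- function(tips, p1 = 0.4, pq = 0.2) {
  states <- sample(c("1", "0", "?"), length(tips), replace = TRUE,
                   prob = c(p1, 1 - p1 - pq, pq))
  setNames(states, tips)
}

## exhaustive enumeration of rooted binary topologies over small tip sets
all_rooted_topologies <- function(tips) {
  trees <- sinephylo:::all_rooted_trees(as.list(tips))
  lapply(trees, function(tr)
    ape::read.tree(text = paste0(sinephylo:::nested_to_newick(tr), ";")))
}
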