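## Irreversible (Camin-Sokal) binary parsimony: only 0 -> 1 changes are
## allowed and the root state is fixed at 0, matching retroposon biology
## (elements integrate irreversibly, precise excision is unknown). With
## missing entries assigned freely, the minimum change count equals the
## number of maximal subtrees whose determinate leaves are all 1; a single
## postorder pass over (has-determinate-1, has-determinate-0) flags finds
## them.

as_state_matrix <- function(x) {
  if (inherits(x, "pa_matrix")) x <- x$states
  if (is.character(x)) {
    m <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
    m[x == "1"] <- 1
    m[x == "0"] <- 0
    x <- m
  }
  x
}

as_character_states <- function(character) {
  if (is.null(names(character))) abort("character states must be named by taxon")
  v <- as.character(unname(character))
  out <- rep(NA_real_, length(v))
  out[v %in% c("1", "TRUE")] <- 1
  out[v %in% c("0", "FALSE")] <- 0
  if (any(!v %in% c("0", "1", "?", "TRUE", "FALSE", NA))) {
    abort("character states must be 0, 1 or ?")
  }
  names(out) <- names(character)
  out
}

## vectorised scorer over a whole matrix; returns per-locus minimum change
## counts and the (parent-impure, child-pure1) origin-edge indicator matrix
cs_engine <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- ncol(states)
  miss <- setdiff(rownames(states), tree$tip.label)
  if (length(miss)) abort(paste("unknown taxa in characters:",
                                paste(miss, collapse = ", ")))
  has1 <- matrix(FALSE, nn, L)
  has0 <- matrix(FALSE, nn, L)
  ts <- states[match(tree$tip.label, rownames(states)), , drop = FALSE]
  has1[seq_len(ntip), ] <- !is.na(ts) & ts == 1
  has0[seq_len(ntip), ] <- !is.na(ts) & ts == 0
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    has1[p, ] <- has1[p, ] | has1[ch, ]
    has0[p, ] <- has0[p, ] | has0[ch, ]
  }
  pure1 <- has1 & !has0
  root <- ntip + 1L
  # a 0 -> 1 change sits on the stem edge of each maximal all-1 subtree;
  # when even the root subtree is 0-free the changes fall on the root's
  # child edges (there is no edge above the root)
  origin <- pure1[po[, 2], , drop = FALSE] &
    (!pure1[po[, 1], , drop = FALSE] |
       matrix(po[, 1] == root, nrow(po), L))
  list(min_changes = colSums(origin),
       origin = origin, edges = po, root_pure1 = pure1[root, ],
       ntip = ntip)
}

#' Score one binary character under Camin-Sokal irreversible parsimony
#'
#' Computes the minimum number of 0 to 1 transitions (1 to 0 forbidden, root
#' fixed at 0) needed to explain the determinate states, with `?` leaves
#' assigned freely, and reports the stem branches of the maximal all-1
#' subtrees where those origins fall.
#'
#' @param tree Rooted `phylo` (polytomies allowed).
#' @param character Named vector of states over `"0"`, `"1"`, `"?"` (or
#'   0/1/NA), names are tip labels. Tips absent from `character` count as
#'   missing.
#' @param locus_id Optional identifier carried into the result.
#' @return A `character_fit`: list with `locus_id`, `min_changes`,
#'   `origin_branches` (list of tip-label sets, one per origin), and
#'   `consistent` (`min_changes <= 1`).
#' @export
camin_sokal_score <- function(tree, character, locus_id = NULL) {
  st <- as_character_states(character)
  m <- matrix(NA_real_, length(tree$tip.label), 1,
              dimnames = list(tree$tip.label, "x"))
  miss <- setdiff(names(st), tree$tip.label)
  if (length(miss)) abort(paste("unknown taxa in character:",
                                paste(miss, collapse = ", ")))
  m[names(st), 1] <- st
  eng <- cs_engine(tree, m)
  sets <- node_tip_sets(tree)
  origins <- lapply(which(eng$origin[, 1]), function(e) sets[[eng$edges[e, 2]]])
  fit <- list(locus_id = locus_id,
              min_changes = unname(eng$min_changes[1]),
              origin_branches = origins,
              consistent = unname(eng$min_changes[1]) <= 1L)
  class(fit) <- "character_fit"
  fit
}

#' @export
print.character_fit <- function(x, ...) {
  cat("Camin-Sokal fit", if (!is.null(x$locus_id)) paste0("(", x$locus_id, ")"),
      ": min changes =", x$min_changes,
      if (x$consistent) "(consistent)" else "(homoplastic)", "\n")
  invisible(x)
}

#' Total Camin-Sokal parsimony score of a matrix on a tree
#'
#' @param tree Rooted `phylo`.
#' @param x A `pa_matrix` or character/numeric state matrix (taxa x loci).
#' @return Tibble with `locus_id` and `min_changes`; the tree score is
#'   `sum(min_changes)`.
#' @export
camin_sokal_matrix <- function(tree, x) {
  states <- as_state_matrix(x)
  eng <- cs_engine(tree, states)
  tibble::tibble(locus_id = colnames(states), min_changes = eng$min_changes)
}

determinate_one_set <- function(character) {
  st <- as_character_states(character)
  names(st)[!is.na(st) & st == 1]
}

#' Are two irreversible binary characters compatible on some rooted tree?
#'
#' For rooted irreversible binary characters, compatibility (both fit with a
#' single origin on one tree) holds iff their determinate 1-sets are nested
#' or disjoint (laminar condition). `?` entries are ignored.
#'
#' @param c1,c2 Named state vectors as in [camin_sokal_score()].
#' @return Logical.
#' @export
check_compatibility <- function(c1, c2) {
  s1 <- determinate_one_set(c1)
  s2 <- determinate_one_set(c2)
  all(s1 %in% s2) || all(s2 %in% s1) || !any(s1 %in% s2)
}

#' Build the perfect phylogeny of a conflict-free insertion matrix
#'
#' If every pair of characters is compatible (1-sets laminar), returns the
#' rooted tree whose clades are exactly the distinct determinate 1-sets (plus
#' the root), with polytomies where unresolved. Otherwise returns the
#' conflicting pairs.
#'
#' @param x A `pa_matrix` or state matrix.
#' @return List with `tree` (`phylo` or `NULL`) and `conflicts` (tibble of
#'   incompatible locus pairs, empty when a tree exists).
#' @export
build_perfect_phylogeny <- function(x) {
  states <- as_state_matrix(x)
  taxa <- rownames(states)
  sets <- lapply(seq_len(ncol(states)), function(j) {
    taxa[!is.na(states[, j]) & states[, j] == 1]
  })
  names(sets) <- colnames(states)
  conflicts <- list()
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      s1 <- sets[[i]]; s2 <- sets[[j]]
      if (!(all(s1 %in% s2) || all(s2 %in% s1) || !any(s1 %in% s2))) {
        conflicts[[length(conflicts) + 1L]] <-
          tibble::tibble(locus1 = names(sets)[j], locus2 = names(sets)[i])
      }
    }
  }
  if (length(conflicts)) {
    return(list(tree = NULL, conflicts = dplyr::bind_rows(conflicts)))
  }
  list(tree = tree_from_clades(sets, taxa),
       conflicts = tibble::tibble(locus1 = character(0), locus2 = character(0)))
}

## ---- tree search over rooted binary ingroup topologies -------------------
## nested-list representation: a leaf is a taxon name, an internal node a
## list of two subtrees; the outgroup is attached at the root afterwards.

nested_to_newick <- function(tr) {
  if (is.character(tr)) return(tr)
  paste0("(", nested_to_newick(tr[[1]]), ",", nested_to_newick(tr[[2]]), ")")
}

nested_min_label <- function(tr) {
  if (is.character(tr)) return(tr)
  min(nested_min_label(tr[[1]]), nested_min_label(tr[[2]]))
}

nested_canonical <- function(tr) {
  if (is.character(tr)) return(tr)
  a <- nested_canonical(tr[[1]]); b <- nested_canonical(tr[[2]])
  if (nested_min_label(tr[[1]]) <= nested_min_label(tr[[2]])) list(a, b) else list(b, a)
}

nested_key <- function(tr) nested_to_newick(nested_canonical(tr))

## Camin-Sokal total score of (outgroup, ingroup-tree) with root state 0;
## returns sum over loci of min changes. states: numeric matrix taxa x L.
score_nested <- function(tr, states, og_has1, og_has0) {
  rec <- function(node) {
    if (is.character(node)) {
      s <- states[node, ]
      return(list(h1 = !is.na(s) & s == 1, h0 = !is.na(s) & s == 0, ch = 0))
    }
    a <- rec(node[[1]]); b <- rec(node[[2]])
    h1 <- a$h1 | b$h1
    h0 <- a$h0 | b$h0
    p <- h1 & !h0
    ch <- a$ch + b$ch +
      sum(a$h1 & !a$h0 & !p) + sum(b$h1 & !b$h0 & !p)
    list(h1 = h1, h0 = h0, ch = ch)
  }
  r <- rec(tr)
  # root children (outgroup leaf, ingroup subtree) receive an origin whenever
  # their subtree is 0-free with a determinate 1 - the root itself is state 0
  # and has no stem edge
  r$ch + sum(r$h1 & !r$h0) + sum(og_has1 & !og_has0)
}

insert_everywhere <- function(tr, leaf) {
  out <- list(list(tr, leaf))
  if (!is.character(tr)) {
    for (left in insert_everywhere(tr[[1]], leaf)) {
      out[[length(out) + 1L]] <- list(left, tr[[2]])
    }
    for (right in insert_everywhere(tr[[2]], leaf)) {
      out[[length(out) + 1L]] <- list(tr[[1]], right)
    }
  }
  out
}

nni_neighbors <- function(tr) {
  out <- list()
  walk <- function(node, replace) {
    if (is.character(node)) return()
    a <- node[[1]]; b <- node[[2]]
    for (side in 1:2) {
      child <- node[[side]]; sib <- node[[3 - side]]
      if (!is.character(child)) {
        # swap each grandchild with the sibling
        out[[length(out) + 1L]] <<- replace(
          if (side == 1) list(list(sib, child[[2]]), child[[1]])
          else list(child[[1]], list(sib, child[[2]])))
        out[[length(out) + 1L]] <<- replace(
          if (side == 1) list(list(child[[1]], sib), child[[2]])
          else list(child[[2]], list(child[[1]], sib)))
      }
    }
    walk(a, function(x) replace(list(x, b)))
    walk(b, function(x) replace(list(a, x)))
  }
  walk(tr, function(x) x)
  out
}

## prune every proper subtree and regraft it on every remaining position
spr_neighbors <- function(tr) {
  subtrees <- list()
  collect <- function(node, context) {
    # context(x) rebuilds the full tree with this subtree replaced by x;
    # NULL x means delete (sibling is spliced up)
    if (!is.character(node)) {
      collect(node[[1]], function(x) {
        if (is.null(x)) context(node[[2]]) else context(list(x, node[[2]]))
      })
      collect(node[[2]], function(x) {
        if (is.null(x)) context(node[[1]]) else context(list(node[[1]], x))
      })
    }
    subtrees[[length(subtrees) + 1L]] <<- list(sub = node, ctx = context)
  }
  collect(tr[[1]], function(x) if (is.null(x)) tr[[2]] else list(x, tr[[2]]))
  collect(tr[[2]], function(x) if (is.null(x)) tr[[1]] else list(tr[[1]], x))
  out <- list()
  for (s in subtrees) {
    pruned <- s$ctx(NULL)
    for (regrafted in insert_everywhere(pruned, s$sub)) {
      out[[length(out) + 1L]] <- regrafted
    }
  }
  out
}

all_rooted_trees <- function(labels) {
  if (length(labels) == 1L) return(list(labels[[1]]))
  prev <- all_rooted_trees(labels[-length(labels)])
  leaf <- labels[[length(labels)]]
  unlist(lapply(prev, insert_everywhere, leaf = leaf), recursive = FALSE)
}

nested_to_phylo <- function(tr, outgroup) {
  nwk <- paste0("(", outgroup, ",", nested_to_newick(tr), ");")
  ape::read.tree(text = nwk)
}

#' Search for minimum-change trees under Camin-Sokal parsimony
#'
#' Finds rooted trees (outgroup attached at the root, root state 0)
#' minimising the total number of 0 to 1 origins over all characters.
#' `exhaustive` enumerates every rooted binary ingroup topology (allowed up
#' to 9 ingroup taxa); `branch_and_bound` prunes partial topologies whose
#' score already exceeds the incumbent (exact); `heuristic` runs
#' random-addition starts followed by NNI to convergence and one SPR round.
#'
#' @param x A `pa_matrix` or state matrix.
#' @param outgroup Taxon attached at the root.
#' @param mode `"exhaustive"`, `"branch_and_bound"` or `"heuristic"`.
#' @param starts Random-addition starts for the heuristic.
#' @param seed Seed controlling heuristic randomness.
#' @return An `mp_search`: list with `trees` (list of `phylo`), `score`,
#'   `mode`.
#' @export
search_mp_trees <- function(x, outgroup,
                            mode = c("heuristic", "branch_and_bound", "exhaustive"),
                            starts = 10L, seed = 1L) {
  mode <- match.arg(mode)
  states <- as_state_matrix(x)
  if (!outgroup %in% rownames(states)) abort("outgroup not in matrix")
  ingroup <- setdiff(rownames(states), outgroup)
  og <- states[outgroup, ]
  og_has1 <- !is.na(og) & og == 1
  og_has0 <- !is.na(og) & og == 0
  scorer <- function(tr) score_nested(tr, states, og_has1, og_has0)

  best <- Inf
  best_trees <- list()
  offer <- function(tr, sc) {
    if (sc < best) {
      best <<- sc
      best_trees <<- setNames(list(tr), nested_key(tr))
    } else if (sc == best) {
      k <- nested_key(tr)
      if (is.null(best_trees[[k]])) best_trees[[k]] <<- tr
    }
  }

  if (mode == "exhaustive") {
    if (length(ingroup) > 9L) abort("exhaustive search limited to 9 ingroup taxa")
    for (tr in all_rooted_trees(as.list(ingroup))) offer(tr, scorer(tr))
  } else if (mode == "branch_and_bound") {
    recurse <- function(tr, remaining) {
      sc <- scorer(tr)
      if (sc > best) return()
      if (!length(remaining)) { offer(tr, sc); return() }
      for (nt in insert_everywhere(tr, remaining[[1]])) {
        recurse(nt, remaining[-1])
      }
    }
    if (length(ingroup) == 1L) {
      offer(ingroup[[1]], scorer(ingroup[[1]]))
    } else {
      recurse(list(ingroup[[1]], ingroup[[2]]), as.list(ingroup[-(1:2)]))
    }
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    for (s in seq_len(starts)) {
      ord <- sample(ingroup)
      tr <- if (length(ord) >= 2) list(ord[[1]], ord[[2]]) else ord[[1]]
      if (length(ord) > 2) {
        for (t in ord[-(1:2)]) {
          cands <- insert_everywhere(tr, t)
          scs <- vapply(cands, scorer, 0)
          tr <- cands[[which.min(scs)]]
        }
      }
      sc <- scorer(tr)
      repeat {
        improved <- FALSE
        repeat {
          nni_better <- FALSE
          for (nb in nni_neighbors(tr)) {
            nsc <- scorer(nb)
            if (nsc < sc) { tr <- nb; sc <- nsc; nni_better <- TRUE }
          }
          if (!nni_better) break
          improved <- TRUE
        }
        if (!is.character(tr)) {
          for (nb in spr_neighbors(tr)) {
            nsc <- scorer(nb)
            if (nsc < sc) { tr <- nb; sc <- nsc; improved <- TRUE }
          }
        }
        if (!improved) break
      }
      offer(tr, sc)
      # also record equal-score NNI neighbours of the local optimum
      if (!is.character(tr)) {
        for (nb in nni_neighbors(tr)) if (scorer(nb) == sc) offer(nb, sc)
      }
    }
  }
  out <- list(trees = lapply(unname(best_trees), nested_to_phylo, outgroup = outgroup),
              score = best, mode = mode, outgroup = outgroup)
  class(out) <- "mp_search"
  out
}

#' @export
print.mp_search <- function(x, ...) {
  cat("Camin-Sokal MP search (", x$mode, "): ", length(x$trees),
      " optimal tree(s), score ", x$score, "\n", sep = "")
  invisible(x)
}

#' @rdname search_mp_trees
#' @param x An `mp_search`.
#' @param ... Unused.
#' @export
tidy.mp_search <- function(x, ...) {
  tibble::tibble(tree = seq_along(x$trees),
                 score = x$score,
                 newick = vapply(x$trees, function(t)
                   ape::write.tree(t), ""))
}

#' @rdname search_mp_trees
#' @export
glance.mp_search <- function(x, ...) {
  tibble::tibble(score = x$score, n_trees = length(x$trees), mode = x$mode)
}

#' Strict consensus of rooted trees
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees List of rooted `phylo` (or `multiPhylo`) on one leaf set.
#' @return Rooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) abort("trees must share one leaf set")
  }
  clade_keys <- function(tree) {
    sets <- node_tip_sets(tree)
    ntip <- length(tree$tip.label)
    keys <- vapply(sets[(ntip + 1L):length(sets)],
                   function(s) paste(sort(s), collapse = "|"), "")
    unique(keys)
  }
  common <- Reduce(intersect, lapply(trees, clade_keys))
  clades <- strsplit(common, "|", fixed = TRUE)
  tree_from_clades(clades, trees[[1]]$tip.label)
}

#' Map insertion synapomorphies onto tree branches
#'
#' Assigns every consistent character (one origin) to its origin branch,
#' identified by the leaf set of the subtree it subtends, and lists
#' characters requiring more than one origin separately for downstream
#' anomaly classification.
#'
#' @param tree Rooted `phylo` whose tips are the matrix taxa.
#' @param x A `pa_matrix` or state matrix.
#' @return List with `branches` (tibble: `clade_label`, `clade` list-column,
#'   `n_loci`, `loci` list-column) and `incongruent` (tibble: `locus_id`,
#'   `min_changes`).
#' @export
map_synapomorphies <- function(tree, x) {
  states <- as_state_matrix(x)
  eng <- cs_engine(tree, states)
  sets <- node_tip_sets(tree)
  rows <- list()
  incon <- list()
  for (j in seq_len(ncol(states))) {
    mc <- eng$min_changes[j]
    if (mc > 1L) {
      incon[[length(incon) + 1L]] <-
        tibble::tibble(locus_id = colnames(states)[j], min_changes = mc)
    } else if (mc == 1L) {
      e <- which(eng$origin[, j])
      clade <- sets[[eng$edges[e, 2]]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = colnames(states)[j],
        clade_label = paste(sort(clade), collapse = "|"),
        clade = list(sort(clade)))
    }
  }
  branches <- if (length(rows)) {
    dplyr::summarise(dplyr::group_by(dplyr::bind_rows(rows), .data$clade_label),
                     clade = list(.data$clade[[1]]),
                     n_loci = dplyr::n(),
                     loci = list(.data$locus_id), .groups = "drop")
  } else {
    tibble::tibble(clade_label = character(0), clade = list(),
                   n_loci = integer(0), loci = list())
  }
  list(branches = dplyr::arrange(branches, dplyr::desc(lengths(.data$clade))),
       incongruent = if (length(incon)) dplyr::bind_rows(incon) else
         tibble::tibble(locus_id = character(0), min_changes = integer(0)))
}
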