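#' Build a locus alignment with element annotations
#'
#' A locus alignment holds one aligned sequence per haplotype (element-bearing
#' taxa carry the element, element-free taxa have gaps across the element
#' columns) plus, per bearing sequence, the alignment-column interval its
#' element occupies. Insertion points are reported on the ungapped coordinate
#' frame of an element-free ("ancestral") sequence, 0-based half-open.
#'
#' @param locus_id Locus identifier.
#' @param aln Character matrix (rows: sequence ids, columns: alignment
#'   columns, entries single characters incl. `-`), or named character vector
#'   of equal-length aligned strings.
#' @param elements Tibble with `seq_id`, `col_start`, `col_end` (1-based
#'   inclusive alignment columns of the element in that sequence), optionally
#'   `taxon` (defaults to `seq_id`).
#' @return A `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, aln, elements) {
  if (is.character(aln) && is.null(dim(aln))) {
    aln <- do.call(rbind, lapply(strsplit(aln, ""), identity)) |>
      (\(m) { rownames(m) <- names(aln); m })()
  }
  elements <- tibble::as_tibble(elements)
  if (!"taxon" %in% names(elements)) elements$taxon <- elements$seq_id
  if (!all(elements$seq_id %in% rownames(aln))) {
    abort("element seq_id not present in alignment")
  }
  structure(list(locus_id = locus_id, aln = aln, elements = elements),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment", x$locus_id, ":", nrow(x$aln), "sequences x",
      ncol(x$aln), "columns;", nrow(x$elements), "element annotation(s)\n")
  invisible(x)
}

## 0-based ancestral-frame coordinate of an alignment column: number of
## non-gap reference characters strictly before that column
anc_position <- function(ref_chars, col) sum(ref_chars[seq_len(col - 1L)] != "-")

element_free_rows <- function(x) {
  setdiff(rownames(x$aln), unique(x$elements$seq_id))
}

#' Detect near-parallel insertions at a locus
#'
#' Two independent integrations can mimic one shared insertion on a gel.
#' Using an element-free sequence to define the ancestral coordinate frame,
#' the call is `near_parallel` when elements map to insertion points >= 1 nt
#' apart, or when elements at one point are too diverged to be the same
#' element (`identity < identity_threshold`); otherwise the insertion is
#' treated as shared/orthologous (`consistent`). Offsets of 1-5 nt are
#' additionally flagged for manual review (possible alignment slippage).
#'
#' @param x A `locus_alignment` with at least one element-free sequence.
#' @param identity_threshold Minimum pairwise element identity for "same
#'   element" (default 0.8).
#' @return One-row tibble: `locus_id`, `category`, `offset_nt`,
#'   `element_identity`, `taxa` (list-column), `review`.
#' @export
detect_near_parallel <- function(x, identity_threshold = 0.8) {
  free <- element_free_rows(x)
  if (!length(free)) {
    abort("no element-free sequence: cannot orient the ancestral frame")
  }
  ref <- x$aln[free[1], ]
  el <- x$elements
  if (nrow(el) == 0L) {
    return(tibble::tibble(locus_id = x$locus_id, category = "consistent",
                          offset_nt = 0L, element_identity = NA_real_,
                          taxa = list(character(0)), review = FALSE))
  }
  pts <- vapply(el$col_start, function(cs) anc_position(ref, cs), 0)
  offset <- max(pts) - min(pts)
  taxa <- unique(el$taxon)
  if (offset >= 1) {
    return(tibble::tibble(locus_id = x$locus_id, category = "near_parallel",
                          offset_nt = as.integer(offset),
                          element_identity = NA_real_, taxa = list(taxa),
                          review = offset <= 5))
  }
  # one site: compare element sequences column-wise
  ident <- 1
  if (nrow(el) >= 2L) {
    pair_id <- function(i, j) {
      ci <- seq(el$col_start[i], el$col_end[i])
      cj <- seq(el$col_start[j], el$col_end[j])
      cols <- intersect(ci, cj)
      a <- x$aln[el$seq_id[i], cols]; b <- x$aln[el$seq_id[j], cols]
      comp <- a != "-" & b != "-"
      if (!sum(comp)) return(0)
      sum(a[comp] == b[comp]) / max(length(ci), length(cj))
    }
    prs <- utils::combn(nrow(el), 2)
    ident <- min(vapply(seq_len(ncol(prs)), function(k)
      pair_id(prs[1, k], prs[2, k]), 0))
  }
  if (ident < identity_threshold) {
    tibble::tibble(locus_id = x$locus_id, category = "near_parallel",
                   offset_nt = 0L, element_identity = ident,
                   taxa = list(taxa), review = FALSE)
  } else {
    tibble::tibble(locus_id = x$locus_id, category = "consistent",
                   offset_nt = 0L, element_identity = ident,
                   taxa = list(taxa), review = FALSE)
  }
}

#' Detect within-species insertion polymorphism
#'
#' Flags every (locus, taxon) showing both allele classes: a heterozygous
#' amplicon profile (two product lengths in one individual) or a mixture of
#' insertion-only and empty-site-only individuals within one species.
#'
#' @param observations Observation tibble (see [code_matrix()]).
#' @return Tibble per polymorphic locus: `locus_id`, `category`
#'   (`"polymorphic"`), `taxa` (list-column of polymorphic taxa).
#' @export
detect_polymorphic_loci <- function(observations) {
  observations <- tibble::as_tibble(observations)
  res <- list()
  for (grp in split(observations,
                    list(observations$locus_id, observations$taxon),
                    drop = TRUE)) {
    het <- if ("amplicon_lengths" %in% names(grp)) {
      any(vapply(grp$amplicon_lengths, function(a) length(unique(a)) >= 2L, TRUE))
    } else FALSE
    det <- unique(grp$state[grp$state != "missing"])
    mixed <- all(c("present", "absent") %in% det)
    if (het || mixed) {
      res[[length(res) + 1L]] <-
        tibble::tibble(locus_id = grp$locus_id[1], taxon = grp$taxon[1])
    }
  }
  if (!length(res)) {
    return(tibble::tibble(locus_id = character(0), category = character(0),
                          taxa = list()))
  }
  dplyr::summarise(dplyr::group_by(dplyr::bind_rows(res), .data$locus_id),
                   category = "polymorphic", taxa = list(.data$taxon),
                   .groups = "drop")
}

#' Classify a conflicting locus and list its candidate explanations
#'
#' Rule-based adjudication of loci whose pattern conflicts with the species
#' tree. Distinct insertion coordinates reclassify the locus as
#' `near_parallel` (removing the homoplasy). A locus fixed in one group and
#' polymorphic in related taxa, compatible with a single origin on the stem
#' of the group spanning both, keeps all three explanations — incomplete
#' lineage sorting, introgression and paralogous insertion — as candidates
#' (none is adjudicated). Remaining characters needing more than one origin
#' are reported as unresolved homoplasy with the same non-empty candidate
#' set. Single-origin loci without polymorphism are `consistent`.
#'
#' @param fit A `character_fit` from [camin_sokal_score()].
#' @param near_parallel_call Optional one-row tibble from
#'   [detect_near_parallel()] for this locus.
#' @param tree Rooted species tree (`phylo`).
#' @param character The named state vector that was scored.
#' @param polymorphic_taxa Character vector of taxa polymorphic at this
#'   locus (e.g. from [detect_polymorphic_loci()]).
#' @return One-row tibble: `locus_id`, `category`, `explanations`
#'   (list-column), `taxa` (list-column), `single_origin_clade` (logical).
#' @export
classify_conflict <- function(fit, tree, character,
                              near_parallel_call = NULL,
                              polymorphic_taxa = character(0)) {
  locus <- fit$locus_id %||% "locus"
  if (!is.null(near_parallel_call) && nrow(near_parallel_call) &&
      near_parallel_call$category[1] == "near_parallel") {
    return(tibble::tibble(locus_id = locus, category = "near_parallel",
                          explanations = list("near_parallel"),
                          taxa = near_parallel_call$taxa,
                          single_origin_clade = NA))
  }
  st <- as_character_states(character)
  carriers <- names(st)[!is.na(st) & st == 1]
  if (length(polymorphic_taxa)) {
    span <- union(carriers, polymorphic_taxa)
    single <- length(span) >= 2 && is_clade(tree, span)
    return(tibble::tibble(
      locus_id = locus, category = "polymorphic",
      explanations = list(c("ils_candidate", "introgression_candidate",
                            "paralog_candidate")),
      taxa = list(polymorphic_taxa), single_origin_clade = single))
  }
  if (fit$min_changes <= 1L) {
    return(tibble::tibble(locus_id = locus, category = "consistent",
                          explanations = list(character(0)),
                          taxa = list(carriers), single_origin_clade = TRUE))
  }
  tibble::tibble(locus_id = locus, category = "unresolved_homoplasy",
                 explanations = list(c("ils_candidate",
                                       "introgression_candidate",
                                       "paralog_candidate")),
                 taxa = list(carriers), single_origin_clade = FALSE)
}

#' Split a near-parallel locus into site-specific characters
#'
#' When sequencing shows that apparent carriers hold an independent element
#' at a distinct nearby site, the single presence/absence column is split:
#' the original character keeps state 1 only for true carriers (the
#' secondary taxa become 0 -- their site is empty at the original
#' coordinate), and a new character records the secondary insertion.
#'
#' @param character Named state vector.
#' @param secondary_taxa Taxa whose element sits at the distinct site.
#' @param ids Length-2 character: ids for the (original, secondary) loci.
#' @return Named list of two state vectors.
#' @export
split_near_parallel <- function(character, secondary_taxa,
                                ids = c("primary", "secondary")) {
  st <- as_character_states(character)
  prim <- st
  prim[secondary_taxa] <- 0
  sec <- st
  sec[] <- ifelse(is.na(st), NA, 0)
  sec[secondary_taxa] <- 1
  to_chr <- function(v) {
    out <- ifelse(is.na(v), "?", as.character(v))
    names(out) <- names(v)
    out
  }
  setNames(list(to_chr(prim), to_chr(sec)), ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
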