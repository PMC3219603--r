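#' Construct a presence/absence character matrix object
#'
#' @param states Character matrix over `"0"`, `"1"`, `"?"`; rows are taxa
#'   (rownames), columns are loci (colnames).
#' @param meta Optional per-locus metadata tibble with at least `locus_id`;
#'   recognised columns: `undecipherable` (logical), `polymorphic_taxa`
#'   (list of character vectors), `source`, `category`.
#' @return A `pa_matrix`.
#' @export
pa_matrix <- function(states, meta = NULL) {
  if (is.null(rownames(states)) ||
      (ncol(states) > 0L && is.null(colnames(states)))) {
    abort("states needs taxon rownames and locus colnames")
  }
  if (anyDuplicated(rownames(states))) abort("duplicate taxa")
  if (anyDuplicated(colnames(states))) abort("duplicate loci")
  if (!all(states %in% c("0", "1", "?"))) abort("states must be 0, 1 or ?")
  if (is.null(meta)) {
    meta <- tibble::tibble(locus_id = colnames(states) %||% character(0))
  }
  meta <- tibble::as_tibble(meta)
  if (!"undecipherable" %in% names(meta)) meta$undecipherable <- FALSE
  if (!"polymorphic_taxa" %in% names(meta)) {
    meta$polymorphic_taxa <- rep(list(character(0)), nrow(meta))
  }
  meta <- meta[match(colnames(states), meta$locus_id), ]
  structure(list(states = states, meta = meta), class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("Presence/absence matrix:", nrow(x$states), "taxa x",
      ncol(x$states), "loci\n")
  tab <- table(factor(x$states, levels = c("0", "1", "?")))
  cat("  states: 0 =", tab[["0"]], " 1 =", tab[["1"]], " ? =", tab[["?"]], "\n")
  npoly <- sum(lengths(x$meta$polymorphic_taxa) > 0)
  if (npoly) cat("  loci with polymorphic taxa:", npoly, "\n")
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$states)

#' Taxa and loci of a presence/absence matrix
#' @param x A `pa_matrix`.
#' @return Character vector.
#' @export
pa_taxa <- function(x) rownames(x$states)

#' @rdname pa_taxa
#' @export
pa_loci <- function(x) colnames(x$states)

#' Tidy a presence/absence matrix into long format
#'
#' @param x A `pa_matrix`.
#' @param ... Unused.
#' @return Tibble with `taxon`, `locus_id`, `state`.
#' @export
tidy.pa_matrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(rownames(x$states), times = ncol(x$states)),
    locus_id = rep(colnames(x$states), each = nrow(x$states)),
    state = as.vector(x$states))
}

combine_obs <- function(df) {
  det <- df$state[df$state != "missing"]
  n_lengths <- if ("amplicon_lengths" %in% names(df)) {
    max(c(0L, vapply(df$amplicon_lengths, function(a)
      length(unique(a)), 1L)), na.rm = TRUE)
  } else 0L
  both_bands <- n_lengths >= 2L
  if (!length(det)) return(list(state = "?", polymorphic = FALSE))
  if (all(det == "present")) {
    return(list(state = "1", polymorphic = both_bands))
  }
  if (all(det == "absent")) return(list(state = "0", polymorphic = FALSE))
  # both present and absent records: polymorphism needs supporting evidence
  inds <- if ("individual_id" %in% names(df)) unique(df$individual_id) else NULL
  if (both_bands || (length(inds) > 1L && !anyNA(inds))) {
    return(list(state = "1", polymorphic = TRUE))
  }
  abort(paste0("conflicting observations for locus ", df$locus_id[1],
               ", taxon ", df$taxon[1], ": ",
               paste(df$state, collapse = "/")))
}

#' Code locus observations into a presence/absence matrix
#'
#' Each (locus, taxon) cell becomes `1` (present), `0` (absent) or `?`
#' (missing / failed amplification). A taxon showing both allele classes —
#' either a record with two amplicon lengths (heterozygous profile) or
#' present and absent records from different individuals — is coded `1` with
#' the taxon retained in the locus's `polymorphic_taxa` metadata. Present and
#' absent records for one (locus, taxon) without such evidence raise an
#' error.
#'
#' @param observations Tibble with `locus_id`, `taxon`, `state` (one of
#'   `"present"`, `"absent"`, `"missing"`), and optionally `amplicon_lengths`
#'   (list-column of integer vectors) and `individual_id`.
#' @param taxa Row order of the matrix; every observed taxon must appear.
#' @param undecipherable Locus ids flagged as uninterpretable (cannot be
#'   derived from the states themselves).
#' @return A `pa_matrix`.
#' @export
code_matrix <- function(observations, taxa, undecipherable = character(0)) {
  observations <- tibble::as_tibble(observations)
  extra <- setdiff(observations$taxon, taxa)
  if (length(extra)) abort(paste("observation taxa not in taxa:",
                                 paste(extra, collapse = ", ")))
  bad <- setdiff(observations$state, c("present", "absent", "missing"))
  if (length(bad)) abort(paste("unknown states:", paste(bad, collapse = ", ")))
  loci <- unique(observations$locus_id)
  states <- matrix("?", length(taxa), length(loci),
                   dimnames = list(taxa, loci))
  poly <- setNames(rep(list(character(0)), length(loci)), loci)
  for (grp in split(observations,
                    list(observations$locus_id, observations$taxon),
                    drop = TRUE)) {
    res <- combine_obs(grp)
    states[grp$taxon[1], grp$locus_id[1]] <- res$state
    if (res$polymorphic) {
      poly[[grp$locus_id[1]]] <- union(poly[[grp$locus_id[1]]], grp$taxon[1])
    }
  }
  meta <- tibble::tibble(
    locus_id = loci,
    undecipherable = loci %in% undecipherable,
    polymorphic_taxa = unname(poly[loci]))
  pa_matrix(states, meta)
}

#' Filter a matrix down to phylogenetically informative loci
#'
#' Removes loci that failed to amplify in every taxon (`failed_all`), loci
#' flagged uninterpretable (`undecipherable`), and loci present in every
#' scored taxon (`present_all`). Everything else — including species-specific
#' insertions — is retained as `informative`.
#'
#' @param x A `pa_matrix`.
#' @param strict_present_all If `FALSE` (default), `present_all` is evaluated
#'   over non-missing entries: a locus that is `1` in every amplifying taxon
#'   but `?` elsewhere carries no grouping signal and is removed. If `TRUE`,
#'   a locus must be `1` in literally every taxon to be removed.
#' @return List with `matrix` (filtered `pa_matrix`, with `category` recorded
#'   in metadata of the input loci) and `report` (tibble of category counts).
#' @export
filter_informative <- function(x, strict_present_all = FALSE) {
  st <- x$states
  n1 <- colSums(st == "1")
  nq <- colSums(st == "?")
  n0 <- colSums(st == "0")
  failed_all <- nq == nrow(st)
  undec <- x$meta$undecipherable & !failed_all
  present_all <- if (strict_present_all) {
    n1 == nrow(st)
  } else {
    n0 == 0 & n1 > 0 & n1 + nq == nrow(st)
  }
  present_all <- present_all & !failed_all & !undec
  category <- dplyr::case_when(
    failed_all ~ "failed_all",
    undec ~ "undecipherable",
    present_all ~ "present_all",
    TRUE ~ "informative")
  counts <- c(sum(failed_all), sum(undec), sum(present_all),
              sum(category == "informative"))
  report <- tibble::tibble(
    category = c("failed_all", "undecipherable", "present_all", "informative"),
    n = counts)
  keep <- category == "informative"
  meta <- dplyr::mutate(x$meta, category = category)
  out <- pa_matrix(x$states[, keep, drop = FALSE], meta[keep, ])
  list(matrix = out, report = report)
}

#' Read locus observations from a TSV file
#'
#' Expected columns: `locus_id`, `taxon`, `state`; optional
#' `amplicon_lengths` (comma-separated integers per cell) and
#' `individual_id`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Observation tibble for [code_matrix()].
#' @export
read_observations_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  if ("amplicon_lengths" %in% names(df)) {
    df$amplicon_lengths <- lapply(strsplit(as.character(df$amplicon_lengths),
                                           ","), function(x) {
      x <- suppressWarnings(as.integer(trimws(x)))
      x[!is.na(x)]
    })
  }
  df
}

#' Write / read a presence/absence matrix in NEXUS format
#'
#' STANDARD datatype, symbols "01", missing "?".
#'
#' @param x A `pa_matrix`.
#' @param path File path.
#' @return `read_pa_nexus()` returns a `pa_matrix` (metadata is not stored in
#'   NEXUS and comes back empty).
#' @export
write_pa_nexus <- function(x, path) {
  rows <- lapply(seq_len(nrow(x$states)), function(i) unname(x$states[i, ]))
  names(rows) <- rownames(x$states)
  ape::write.nexus.data(rows, path, format = "standard", interleaved = FALSE)
  invisible(path)
}

#' @rdname write_pa_nexus
#' @export
read_pa_nexus <- function(path) {
  rows <- ape::read.nexus.data(path)
  states <- do.call(rbind, lapply(rows, as.character))
  rownames(states) <- names(rows)
  colnames(states) <- paste0("locus", seq_len(ncol(states)))
  pa_matrix(states)
}
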