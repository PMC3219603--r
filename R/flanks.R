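#' Concatenate element-free flanking regions across loci
#'
#' Removes every alignment column touched by a retroposed element, then
#' columns whose gap fraction exceeds `gap_threshold`, and concatenates the
#' remaining flanking columns across loci so that downstream dating is fully
#' independent of the insertions themselves. Taxa missing from a locus are
#' filled with N (and logged).
#'
#' @param loci List of [locus_alignment()] objects (rows named by taxon).
#' @param taxa Taxon set of the output; defaults to the union over loci.
#' @param gap_threshold Columns with a gap ('-') fraction above this are
#'   dropped (default 0.5).
#' @return A `flank_alignment`: list with `aln` (character matrix taxa x
#'   sites), `partitions` (tibble: locus_id, start, end, 1-based inclusive),
#'   and `removal_log` (tibble per locus: columns in, element columns
#'   removed, gapped columns removed, columns retained, taxa filled).
#' @export
concatenate_flanks <- function(loci, taxa = NULL, gap_threshold = 0.5) {
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(loci, function(l) rownames(l$aln))))
  }
  blocks <- list()
  logs <- list()
  pos <- 0L
  parts <- list()
  for (l in loci) {
    aln <- l$aln
    ncol_in <- ncol(aln)
    elem_cols <- integer(0)
    if (nrow(l$elements)) {
      elem_cols <- unique(unlist(Map(seq, l$elements$col_start, l$elements$col_end)))
    }
    keep1 <- setdiff(seq_len(ncol(aln)), elem_cols)
    sub <- aln[, keep1, drop = FALSE]
    gapfrac <- colMeans(sub == "-")
    keep2 <- which(gapfrac <= gap_threshold)
    sub <- sub[, keep2, drop = FALSE]
    filled <- setdiff(taxa, rownames(sub))
    block <- matrix("N", length(taxa), ncol(sub), dimnames = list(taxa, NULL))
    present <- intersect(taxa, rownames(sub))
    block[present, ] <- sub[present, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- block
    if (ncol(block)) {
      parts[[length(parts) + 1L]] <- tibble::tibble(
        locus_id = l$locus_id, start = pos + 1L, end = pos + ncol(block))
      pos <- pos + ncol(block)
    }
    logs[[length(logs) + 1L]] <- tibble::tibble(
      locus_id = l$locus_id, columns_in = ncol_in,
      element_columns_removed = length(elem_cols),
      gapped_columns_removed = length(keep1) - length(keep2),
      columns_retained = ncol(sub),
      taxa_filled = list(filled))
  }
  aln <- do.call(cbind, blocks)
  rownames(aln) <- taxa
  structure(list(aln = aln,
                 partitions = if (length(parts)) dplyr::bind_rows(parts) else
                   tibble::tibble(locus_id = character(0), start = integer(0),
                                  end = integer(0)),
                 removal_log = dplyr::bind_rows(logs)),
            class = "flank_alignment")
}

#' @export
print.flank_alignment <- function(x, ...) {
  cat("Flank alignment:", nrow(x$aln), "taxa x", ncol(x$aln), "sites from",
      nrow(x$removal_log), "loci\n")
  cat("  element columns removed:", sum(x$removal_log$element_columns_removed),
      "; gapped columns removed:", sum(x$removal_log$gapped_columns_removed), "\n")
  invisible(x)
}

#' Write a flank alignment to FASTA
#' @param x A `flank_alignment`.
#' @param path Output path.
#' @export
write_flank_fasta <- function(x, path) {
  write_fasta(setNames(apply(x$aln, 1, paste, collapse = ""), rownames(x$aln)),
              path)
}
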