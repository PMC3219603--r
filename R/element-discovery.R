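#' Normalise genome sequences into a tidy table
#'
#' Accepts a tibble with `id` and `residues` columns (optionally `taxon`), a
#' named character vector, or a [Biostrings::DNAStringSet]. Residues are
#' upper-cased and checked against the IUPAC DNA alphabet.
#'
#' @param genomes Sequences in any of the accepted forms.
#' @return A tibble with columns `id`, `residues`, `taxon`.
#' @export
as_genome_tbl <- function(genomes) {
  if (inherits(genomes, "DNAStringSet")) {
    genomes <- tibble::tibble(id = names(genomes), residues = as.character(genomes))
  } else if (is.character(genomes)) {
    ids <- names(genomes)
    if (is.null(ids)) ids <- paste0("seq", seq_along(genomes))
    genomes <- tibble::tibble(id = ids, residues = unname(genomes))
  } else {
    genomes <- tibble::as_tibble(genomes)
  }
  if (!all(c("id", "residues") %in% names(genomes))) {
    abort("genomes must provide 'id' and 'residues' columns")
  }
  if (!"taxon" %in% names(genomes)) genomes$taxon <- genomes$id
  genomes$residues <- toupper(genomes$residues)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", genomes$residues)
  if (any(bad)) {
    abort(paste0("non-IUPAC characters in sequence(s): ",
                 paste(genomes$id[bad], collapse = ", ")))
  }
  if (any(!nzchar(genomes$residues))) abort("empty sequence not allowed")
  genomes[, c("id", "residues", "taxon")]
}

#' Read genome or consensus FASTA into a tidy sequence table
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Tibble with `id`, `residues`, `taxon` columns.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome_tbl(x)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or tibble with `id`/`residues`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$residues, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## Greedy overlap resolution shared by the scanner and the brute-force test
## oracle: candidates ranked by (longer TSD, longer element, leftmost start);
## a candidate is kept only if its full footprint (left TSD through right TSD)
## is disjoint from every already-kept footprint.
resolve_tsd_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  ord <- order(-cand$tsd_length, -(cand$element_end - cand$element_start),
               cand$element_start)
  cand <- cand[ord, ]
  fs <- cand$left_tsd_start
  fe <- cand$right_tsd_end
  keep <- logical(nrow(cand))
  ks <- ke <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(fs[i] < ke & fe[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, fs[i]); ke <- c(ke, fe[i])
    }
  }
  cand[keep, ]
}

scan_tsd_one <- function(s, min_len, max_len, min_tsd, max_tsd) {
  n <- nchar(s)
  rows_i <- integer(0); rows_j <- integer(0); rows_k <- integer(0)
  for (k in min_tsd:max_tsd) {
    if (n < 2L * k + min_len) break
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    # windows containing anything but A/C/G/T (incl. N) never match
    idx <- which(!grepl("[^ACGT]", kmers))
    if (length(idx) < 2L) next
    grp <- split(idx, kmers[idx])
    grp <- grp[lengths(grp) >= 2L]
    for (pos in grp) {
      # right TSD start j must satisfy element length j - i - k in [min,max]
      lo <- findInterval(pos + k + min_len - 1L, pos) + 1L
      hi <- findInterval(pos + k + max_len, pos)
      take <- which(hi >= lo)
      for (t in take) {
        js <- pos[lo[t]:hi[t]]
        rows_i <- c(rows_i, rep.int(pos[t], length(js)))
        rows_j <- c(rows_j, js)
        rows_k <- c(rows_k, rep.int(k, length(js)))
      }
    }
  }
  if (!length(rows_i)) return(empty_candidates())
  cand <- tibble::tibble(
    left_tsd_start = rows_i - 1L,
    left_tsd_end = rows_i - 1L + rows_k,
    element_start = rows_i - 1L + rows_k,
    element_end = rows_j - 1L,
    right_tsd_start = rows_j - 1L,
    right_tsd_end = rows_j - 1L + rows_k,
    tsd_length = rows_k
  )
  # maximality: one candidate per element interval, longest flanking repeat
  cand <- dplyr::slice_max(
    dplyr::group_by(cand, .data$element_start, .data$element_end),
    .data$tsd_length, n = 1L, with_ties = FALSE)
  dplyr::ungroup(cand)
}

empty_candidates <- function() {
  tibble::tibble(
    left_tsd_start = integer(0), left_tsd_end = integer(0),
    element_start = integer(0), element_end = integer(0),
    right_tsd_start = integer(0), right_tsd_end = integer(0),
    tsd_length = integer(0))
}

#' Scan sequences for candidate retroposed elements flanked by perfect TSDs
#'
#' Finds every interval of `min_len`..`max_len` nt whose immediate flanks are
#' identical direct repeats (target-site duplications) of `min_tsd`..`max_tsd`
#' nt. Repeats must be exactly adjacent to the element, exact matches only;
#' windows containing any non-ACGT code never match. For a fixed element
#' interval only the longest flanking repeat (up to `max_tsd`) is reported;
#' overlapping candidates are then resolved greedily, preferring longer TSDs,
#' then longer elements, then the leftmost start. All coordinates are 0-based,
#' half-open. Element length is measured between the two repeats, excluding
#' both TSD copies.
#'
#' @param genomes Sequences (see [as_genome_tbl()]).
#' @param min_len,max_len Element length bounds in nt (defaults 100 and 500).
#' @param min_tsd,max_tsd TSD length bounds in nt (defaults 8 and 25).
#' @param resolve If `FALSE`, skip overlap resolution and return all maximal
#'   candidates (used for expected-count calculations).
#' @return Tibble of candidates, sorted by element start then element length:
#'   `source_id`, interval columns, `tsd_length`, `tsd_sequence`.
#' @export
scan_tsd_candidates <- function(genomes, min_len = 100L, max_len = 500L,
                                min_tsd = 8L, max_tsd = 25L, resolve = TRUE) {
  if (min_len < 1L || min_len > max_len) abort("need 1 <= min_len <= max_len")
  if (min_tsd < 1L || min_tsd > max_tsd) abort("need 1 <= min_tsd <= max_tsd")
  genomes <- as_genome_tbl(genomes)
  res <- purrr::map2(genomes$id, genomes$residues, function(id, s) {
    cand <- scan_tsd_one(s, min_len, max_len, min_tsd, max_tsd)
    if (resolve) cand <- resolve_tsd_overlaps(cand)
    if (nrow(cand)) {
      cand$source_id <- id
      cand$tsd_sequence <- substring(s, cand$left_tsd_start + 1L, cand$left_tsd_end)
    } else {
      cand$source_id <- character(0)
      cand$tsd_sequence <- character(0)
    }
    cand
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::arrange(out, .data$source_id, .data$element_start,
                        .data$element_end - .data$element_start)
  dplyr::relocate(out, "source_id")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Annotate candidate elements against a consensus library
#'
#' Aligns each candidate element locally (Smith-Waterman, both strands)
#' against every library consensus and keeps the best-scoring hit meeting the
#' identity and coverage thresholds; candidates with no qualifying hit are
#' marked `"unclassified"`. Ties are broken deterministically by library
#' order, then by the plus strand.
#'
#' @param candidates Candidate tibble from [scan_tsd_candidates()].
#' @param genomes The scanned sequences (to extract element sequence).
#' @param library Consensus library: tibble with `family` and `consensus`
#'   columns, or a named character vector.
#' @param min_identity,min_coverage Fractions in (0, 1]. Identity is computed
#'   over the aligned region; coverage is the aligned fraction of the element.
#' @return `candidates` with `family`, `identity`, `coverage`, `score`,
#'   `strand` columns filled.
#' @export
classify_candidates <- function(candidates, genomes, library,
                                min_identity = 0.8, min_coverage = 0.8) {
  if (min_identity <= 0 || min_identity > 1 || min_coverage <= 0 || min_coverage > 1) {
    abort("thresholds must lie in (0, 1]")
  }
  genomes <- as_genome_tbl(genomes)
  if (is.character(library)) {
    library <- tibble::tibble(family = names(library), consensus = unname(library))
  }
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, family = character(0), identity = numeric(0),
                         coverage = numeric(0), score = numeric(0), strand = character(0)))
  }
  seqs <- setNames(genomes$residues, genomes$id)
  elem <- unname(substring(seqs[candidates$source_id],
                           candidates$element_start + 1L,
                           candidates$element_end))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ann <- purrr::map(elem, function(e) {
    best <- NULL
    if (nrow(library)) {
      for (i in seq_len(nrow(library))) {
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") library$consensus[i] else rc(library$consensus[i])
          al <- Biostrings::pairwiseAlignment(
            e, subj, type = "local", substitutionMatrix = mat,
            gapOpening = 4, gapExtension = 1)
          pat <- as.character(Biostrings::alignedPattern(al))
          sub <- as.character(Biostrings::alignedSubject(al))
          p <- strsplit(pat, "")[[1]]; q <- strsplit(sub, "")[[1]]
          alen <- length(p)
          ident <- if (alen) sum(p == q & p != "-") / alen else 0
          cov <- sum(p != "-") / nchar(e)
          sc <- Biostrings::score(al)
          if (ident >= min_identity && cov >= min_coverage &&
              (is.null(best) || sc > best$score)) {
            best <- list(family = library$family[i], identity = ident,
                         coverage = cov, score = sc, strand = strand)
          }
        }
      }
    }
    if (is.null(best)) {
      list(family = "unclassified", identity = NA_real_, coverage = NA_real_,
           score = NA_real_, strand = NA_character_)
    } else best
  })
  dplyr::mutate(candidates,
                family = purrr::map_chr(ann, "family"),
                identity = purrr::map_dbl(ann, "identity"),
                coverage = purrr::map_dbl(ann, "coverage"),
                score = purrr::map_dbl(ann, "score"),
                strand = purrr::map_chr(ann, "strand"))
}

#' Extract a locus region (element plus flanks) around each candidate
#'
#' @param genomes Source sequences.
#' @param candidates Candidate tibble.
#' @param flank Flank width in nt (>= 0); truncated at sequence boundaries.
#' @return Tibble with element and flank sequences and 0-based half-open
#'   coordinates of the full extracted region.
#' @export
extract_locus_region <- function(genomes, candidates, flank = 0L) {
  if (flank < 0L) abort("flank must be >= 0")
  genomes <- as_genome_tbl(genomes)
  seqs <- setNames(genomes$residues, genomes$id)
  n <- nchar(seqs)[candidates$source_id]
  if (any(candidates$element_start < 0L | candidates$element_end > n |
          candidates$left_tsd_start < 0L | candidates$right_tsd_end > n)) {
    abort("candidate coordinates fall outside the source sequence")
  }
  fs <- pmax(0L, candidates$left_tsd_start - flank)
  fe <- pmin(n, candidates$right_tsd_end + flank)
  tibble::tibble(
    source_id = candidates$source_id,
    element_seq = unname(substring(seqs[candidates$source_id],
                                   candidates$element_start + 1L,
                                   candidates$element_end)),
    left_flank = unname(substring(seqs[candidates$source_id], fs + 1L,
                                  candidates$left_tsd_start)),
    right_flank = unname(substring(seqs[candidates$source_id],
                                   candidates$right_tsd_end + 1L, fe)),
    region_start = as.integer(unname(fs)), region_end = as.integer(unname(fe)),
    element_start = candidates$element_start, element_end = candidates$element_end)
}

#' Write a candidate table as BED6
#'
#' Element intervals (0-based half-open) with the TSD length as score.
#'
#' @param candidates Candidate tibble (after [classify_candidates()] if
#'   family/strand are wanted).
#' @param path Output path.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(
    chrom = candidates$source_id,
    start = candidates$element_start,
    end = candidates$element_end,
    name = if ("family" %in% names(candidates)) candidates$family
           else paste0("tsd", candidates$tsd_length),
    score = candidates$tsd_length,
    strand = if ("strand" %in% names(candidates))
      ifelse(is.na(candidates$strand), ".", candidates$strand) else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
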