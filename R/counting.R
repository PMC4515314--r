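#' Per-site allele counts from filtered alignments
#'
#' For each requested site, counts quality-passing read observations of the
#' two catalogued alleles.  Only bases with Phred quality strictly greater
#' than `min_base_quality` (default 30) are considered; observations of any
#' third base go to `n_other`.  Sites with no passing observations are
#' reported with zero counts.
#'
#' @param alignments Alignment tibble that has passed [filter_alignments()]
#'   and [remove_duplicates()].
#' @param sites Tibble with columns `contig`, `pos`, `allele1` (genome
#'   allele), `allele2` (alternate allele) and `site_class` (one of
#'   `known_het`, `common_variant`, `predicted_het`).
#' @param min_base_quality Strict lower bound on base quality; default 30.
#' @return Tibble `contig`, `pos`, `allele1`, `allele2`, `n1`, `n2`,
#'   `n_other`, `site_class`.
#' @export
pileup_alleles <- function(alignments, sites, min_base_quality = 30) {
  sites <- tibble::as_tibble(sites)
  if (!"site_class" %in% names(sites)) sites$site_class <- "known_het"
  bad <- is.na(sites$allele2) & sites$site_class != "predicted_het"
  if (any(bad)) {
    i <- which(bad)[1]
    stop("site ", sites$contig[i], ":", sites$pos[i],
         " has no alternate allele and is not a predicted het", call. = FALSE)
  }
  sites <- sites[, c("contig", "pos", "allele1", "allele2", "site_class")]

  obs <- expand_alignments(alignments)
  obs <- obs[obs$qual > min_base_quality, ]
  obs <- dplyr::inner_join(obs, sites, by = c("contig", "pos"))
  counted <- obs |>
    dplyr::group_by(.data$contig, .data$pos) |>
    dplyr::summarise(n1 = sum(.data$base == .data$allele1),
                     n2 = sum(.data$base == .data$allele2),
                     n_other = sum(.data$base != .data$allele1 &
                                     .data$base != .data$allele2),
                     .groups = "drop")
  sites |>
    dplyr::left_join(counted, by = c("contig", "pos")) |>
    dplyr::mutate(dplyr::across(c("n1", "n2", "n_other"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::select("contig", "pos", "allele1", "allele2", "n1", "n2",
                  "n_other", "site_class") |>
    dplyr::arrange(.data$contig, .data$pos)
}

#' Allele-swap mappability filter
#'
#' Mappability bias — reads carrying one allele mapping uniquely while reads
#' carrying the other map to multiple places — manufactures artificial
#' imbalance.  For every read overlapping a sidecar site, a synthetic copy
#' with that site's base swapped to the other allele is re-aligned
#' (allele-aware); the read is retained only if every swapped copy again
#' maps uniquely to the same locus.  Reads overlapping several sites are
#' swapped one site at a time.  Reads overlapping no sidecar site are kept
#' unconditionally.
#'
#' @param alignments Unique-status alignment tibble.
#' @param ref A [custom_reference()].
#' @param max_mismatch Mismatch budget used for the re-alignment; default 1.
#' @return The filtered alignment tibble.
#' @export
mappability_filter <- function(alignments, ref, max_mismatch = 1) {
  sc <- ref$sidecar
  if (nrow(alignments) == 0 || nrow(sc) == 0) return(alignments)
  stopifnot(all(alignments$status == "unique"))

  agr <- GenomicRanges::GRanges(
    alignments$contig,
    IRanges::IRanges(alignments$start, width = nchar(alignments$seq_fwd)))
  sgr <- GenomicRanges::GRanges(sc$contig, IRanges::IRanges(sc$pos, sc$pos))
  hits <- GenomicRanges::findOverlaps(agr, sgr)
  if (length(hits) == 0) return(alignments)

  ai <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  off <- sc$pos[si] - alignments$start[ai] + 1L
  cur <- substring(alignments$seq_fwd[ai], off, off)
  swap <- ifelse(cur == sc$alt_allele[si], sc$genome_allele[si],
                 sc$alt_allele[si])
  swapped <- alignments$seq_fwd[ai]
  for (k in seq_along(swapped)) substr(swapped[k], off[k], off[k]) <- swap[k]

  res <- cpp_align_reads(swapped, unname(ref$genome), alt_masks(ref),
                         as.integer(max_mismatch), TRUE)
  ok <- res$status == 0L &
    names(ref$genome)[res$contig] == alignments$contig[ai] &
    res$pos0 + 1L == alignments$start[ai]
  ok[is.na(ok)] <- FALSE
  failed <- unique(ai[!ok])
  if (length(failed) == 0) return(alignments)
  alignments[-failed, ]
}

#' Read or write an allele count table
#'
#' TSV with columns `contig pos allele1 allele2 n1 n2 n_other site_class`,
#' sorted by contig then position.
#'
#' @param counts Count tibble from [pileup_alleles()].
#' @param path File path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()` the
#'   count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(dplyr::arrange(counts, .data$contig, .data$pos), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_integer(),
    allele1 = readr::col_character(), allele2 = readr::col_character(),
    n1 = readr::col_integer(), n2 = readr::col_integer(),
    n_other = readr::col_integer(), site_class = readr::col_character()))
}
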