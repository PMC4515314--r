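#' FASTQ input and output
#'
#' Reads are handled as a tibble with columns `id`, `seq` and `qual`
#' (Phred+33 quality string of the same length as `seq`).
#'
#' @param path FASTQ path.
#' @return `read_fastq()` returns the read tibble.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  tibble::tibble(id = sub("\\s.*$", "", names(dss)),
                 seq = unname(as.character(dss)),
                 qual = unname(as.character(S4Vectors::mcols(dss)$qualities)))
}

#' @rdname read_fastq
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Read quality control
#'
#' Mirrors standard fastx-style pre-processing: each read is truncated to its
#' first `trim_to` bases, then retained only if at least `min_fraction` of
#' its (trimmed) bases have a Phred quality of `min_q` or more.  Defaults
#' (`min_q = 20`, `min_fraction = 0.9`) correspond to the usual
#' "90 % of bases at Q20" filter.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param trim_to Target read length; `NULL` keeps the full length.
#' @param min_q Minimum per-base Phred score counted as "good".
#' @param min_fraction Minimum fraction of good bases required to keep a read.
#' @return The filtered read tibble.
#' @export
qc_reads <- function(reads, trim_to = NULL, min_q = 20, min_fraction = 0.9) {
  stopifnot(is.null(trim_to) || trim_to >= 1)
  if (nrow(reads) == 0) return(reads)
  if (!is.null(trim_to)) {
    reads$seq <- substr(reads$seq, 1L, trim_to)
    reads$qual <- substr(reads$qual, 1L, trim_to)
  }
  frac_good <- vapply(phred_scores(reads$qual),
                      function(q) mean(q >= min_q), numeric(1))
  reads[frac_good >= min_fraction, ]
}
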