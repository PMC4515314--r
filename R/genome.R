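#' Genome sequences as named character vectors
#'
#' A genome is represented as a named character vector of uppercase base
#' strings over `A/C/G/T/N`, one element per contig.  These helpers validate,
#' read and write that representation; FASTA I/O is delegated to
#' \pkg{Biostrings}.
#'
#' @param x Named character vector of contig sequences.
#' @return `as_genome()` returns the validated vector.
#' @examples
#' g <- as_genome(c(chr1 = "ACGTACGT"))
#' genome_base(g, "chr1", 3)
#' @export
as_genome <- function(x) {
  if (!is.character(x) || is.null(names(x)) || any(names(x) == "") ||
      anyDuplicated(names(x)) > 0) {
    stop("a genome must be a character vector with unique, non-empty contig names",
         call. = FALSE)
  }
  x <- toupper(x)
  if (any(nchar(x) == 0)) stop("empty contig sequence", call. = FALSE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("contig ", names(x)[bad][1], " contains characters outside A/C/G/T/N",
         call. = FALSE)
  }
  x
}

#' @rdname as_genome
#' @param path Path to a FASTA file.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  g <- as.character(seqs)
  # keep only the first whitespace-delimited token of each FASTA header
  names(g) <- sub("\\s.*$", "", names(seqs))
  as_genome(g)
}

#' @rdname as_genome
#' @param genome Genome vector (see `as_genome()`).
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' @rdname as_genome
#' @param contig,pos Vectors of contig names and 1-based positions.
#' @export
genome_base <- function(genome, contig, pos) {
  stopifnot(all(contig %in% names(genome)))
  unname(substring(genome[contig], pos, pos))
}

# In-place single-base substitution, vectorized over sites.
set_genome_base <- function(genome, contig, pos, base) {
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    s <- genome[[ct]]
    for (k in i) substr(s, pos[k], pos[k]) <- base[k]
    genome[[ct]] <- s
  }
  genome
}

other_bases <- function(base) {
  lapply(base, function(b) setdiff(c("A", "C", "G", "T"), b))
}

#' Reverse-complement a vector of base strings
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
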