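#' Allele-aware ungapped alignment
#'
#' Places each read on the reference by exhaustive ungapped scan over every
#' position and both strands.  A candidate placement's mismatch count treats
#' a read base at a sidecar site as a match when it equals the genome base
#' or, with `allele_aware = TRUE`, the sidecar base — removing the reference
#' mapping bias that otherwise penalizes reads carrying the non-reference
#' allele.  A read is `unique` when exactly one placement attains the
#' minimum mismatch count (and that count is at most `max_mismatch`),
#' `multimapped` when several do, and `unmapped` otherwise.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param ref A [custom_reference()].
#' @param max_mismatch Maximum mismatches allowed (indels are never allowed);
#'   default 1.
#' @param allele_aware Treat sidecar alleles as matches; default `TRUE`.
#' @return An alignment tibble with columns `read_id`, `status`
#'   (`unique`/`multimapped`/`unmapped`), `contig`, `start` (1-based),
#'   `strand`, `mismatches`, `cigar`, and the placed sequence/qualities in
#'   forward-genome orientation (`seq_fwd`, `qual_fwd`).
#' @export
align_reads <- function(reads, ref, max_mismatch = 1, allele_aware = TRUE) {
  genome <- ref$genome
  res <- cpp_align_reads(reads$seq, unname(genome), alt_masks(ref),
                         as.integer(max_mismatch), isTRUE(allele_aware))
  status <- c("unique", "multimapped", "unmapped")[res$status + 1L]
  fwd <- res$forward
  out <- tibble::tibble(
    read_id = reads$id,
    status = status,
    contig = names(genome)[res$contig],
    start = res$pos0 + 1L,
    strand = dplyr::case_when(is.na(fwd) ~ NA_character_,
                              fwd ~ "+", TRUE ~ "-"),
    mismatches = res$mismatches,
    cigar = ifelse(status == "unique", paste0(nchar(reads$seq), "M"),
                   NA_character_),
    seq_fwd = ifelse(!is.na(fwd) & !fwd, revcomp(reads$seq), reads$seq),
    qual_fwd = ifelse(!is.na(fwd) & !fwd, stringi_rev(reads$qual), reads$qual)
  )
  out$seq_fwd[status != "unique"] <- NA_character_
  out$qual_fwd[status != "unique"] <- NA_character_
  out
}

stringi_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Per-contig string with the sidecar allele at variant positions, '.'
# elsewhere; consumed by the C++ aligner.
alt_masks <- function(ref) {
  genome <- ref$genome
  masks <- vapply(nchar(genome),
                  function(n) paste(rep(".", n), collapse = ""), character(1))
  names(masks) <- names(genome)
  sc <- ref$sidecar
  if (nrow(sc) > 0) masks <- set_genome_base(masks, sc$contig, sc$pos,
                                             sc$alt_allele)
  unname(masks[names(genome)])
}

#' Read a blacklist BED file
#'
#' @param path BED path (0-based half-open on disk; returned 1-based
#'   inclusive).
#' @return Tibble with columns `contig`, `start`, `end`.
#' @export
read_blacklist <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr))
}

#' Post-alignment filtering
#'
#' Retains only uniquely mapped reads whose interval does not intersect any
#' blacklist region (multi-mapping reads and reads in underrepresented or
#' copy-number-variable regions both distort allele counts).
#'
#' @param alignments Alignment tibble from [align_reads()] or [ingest_sam()].
#' @param blacklist Optional tibble `contig`, `start`, `end` (1-based
#'   inclusive) from [read_blacklist()].
#' @return The filtered alignment tibble.
#' @export
filter_alignments <- function(alignments, blacklist = NULL) {
  out <- alignments[alignments$status == "unique", ]
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(out) == 0) return(out)
  agr <- GenomicRanges::GRanges(
    out$contig,
    IRanges::IRanges(out$start, width = nchar(out$seq_fwd)))
  bgr <- GenomicRanges::GRanges(
    blacklist$contig, IRanges::IRanges(blacklist$start, blacklist$end))
  hits <- GenomicRanges::countOverlaps(agr, bgr)
  out[hits == 0, ]
}

#' Remove PCR duplicates
#'
#' Among reads sharing the same (contig, strand-aware 5' position, strand),
#' keeps exactly one: the read with the highest base-quality sum, ties broken
#' by lexicographically smallest read id.  Idempotent.
#'
#' @param alignments Unique-status alignment tibble.
#' @return The deduplicated alignment tibble.
#' @export
remove_duplicates <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  stopifnot(all(alignments$status == "unique"))
  len <- nchar(alignments$seq_fwd)
  five_prime <- ifelse(alignments$strand == "+", alignments$start,
                       alignments$start + len - 1L)
  qsum <- vapply(phred_scores(alignments$qual_fwd), sum, numeric(1))
  alignments |>
    dplyr::mutate(.fp = five_prime, .qs = qsum) |>
    dplyr::arrange(.data$contig, .data$.fp, .data$strand,
                   dplyr::desc(.data$.qs), .data$read_id) |>
    dplyr::distinct(.data$contig, .data$.fp, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::select(-".fp", -".qs")
}

#' Write unique alignments as SAM
#'
#' Minimal SAM writer (mandatory columns plus the `NM` tag) for the
#' micro-aligner's output; non-unique reads are skipped.
#'
#' @param alignments Alignment tibble.
#' @param ref A [custom_reference()] (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref, path) {
  genome <- ref$genome
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)))
  aln <- alignments[alignments$status == "unique", ]
  aln <- dplyr::arrange(aln, match(.data$contig, names(genome)), .data$start,
                        .data$read_id)
  body <- character(0)
  if (nrow(aln) > 0) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    body <- paste(aln$read_id, flag, aln$contig, aln$start, 60L, aln$cigar,
                  "*", 0L, 0L, aln$seq_fwd, aln$qual_fwd,
                  paste0("NM:i:", aln$mismatches), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Ingest externally produced alignments from SAM
#'
#' Converts a SAM file (e.g. from a production allele-aware aligner) into the
#' package's alignment tibble via \pkg{Rsamtools}.  Secondary and
#' supplementary records are marked `multimapped`; unmapped records
#' `unmapped`; mismatch counts are taken from the `NM` tag.  Sequences come
#' back in forward-genome orientation as SAM stores them.
#'
#' @param path SAM path.
#' @param ref A [custom_reference()] (unused for parsing; kept so callers can
#'   hand one pipeline state around).
#' @return An alignment tibble.
#' @export
ingest_sam <- function(path, ref = NULL) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq",
             "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0) {
    return(tibble::tibble(read_id = character(), status = character(),
                          contig = character(), start = integer(),
                          strand = character(), mismatches = integer(),
                          cigar = character(), seq_fwd = character(),
                          qual_fwd = character()))
  }
  flag <- b$flag
  status <- dplyr::case_when(
    bitwAnd(flag, 4L) > 0L ~ "unmapped",
    bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L ~ "multimapped",
    TRUE ~ "unique")
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  out <- tibble::tibble(
    read_id = b$qname,
    status = status,
    contig = as.character(b$rname),
    start = b$pos,
    strand = as.character(b$strand),
    mismatches = as.integer(nm),
    cigar = b$cigar,
    seq_fwd = as.character(b$seq),
    qual_fwd = as.character(b$qual))
  out$contig[status == "unmapped"] <- NA_character_
  out$seq_fwd[status != "unique"] <- NA_character_
  out$qual_fwd[status != "unique"] <- NA_character_
  out
}

# Walk a CIGAR string into aligned (ref_pos, read_pos) pairs for M/=/X runs.
# Insertions, deletions, clips and skips consume only one side, so bases at
# or beyond them stop being a simple offset of the start coordinate.
cigar_pairs <- function(cigar, start) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  len <- as.integer(ops[, 2])
  op <- ops[, 3]
  ref_pos <- start
  read_pos <- 1L
  refs <- integer(0)
  reads <- integer(0)
  for (k in seq_along(op)) {
    l <- len[k]
    if (op[k] %in% c("M", "=", "X")) {
      refs <- c(refs, ref_pos + 0:(l - 1L))
      reads <- c(reads, read_pos + 0:(l - 1L))
      ref_pos <- ref_pos + l
      read_pos <- read_pos + l
    } else if (op[k] %in% c("D", "N")) {
      ref_pos <- ref_pos + l
    } else if (op[k] %in% c("I", "S")) {
      read_pos <- read_pos + l
    } # H, P consume nothing we track
  }
  list(ref = refs, read = reads)
}

# Per-base expansion of unique alignments: one row per aligned base with its
# forward-strand reference position, observed base and Phred score.
expand_alignments <- function(alignments) {
  aln <- alignments[alignments$status == "unique", ]
  if (nrow(aln) == 0) {
    return(tibble::tibble(read_id = character(), contig = character(),
                          pos = integer(), base = character(),
                          qual = integer()))
  }
  simple <- grepl("^\\d+M$", aln$cigar)
  pieces <- list()

  if (any(simple)) {
    a <- aln[simple, ]
    L <- nchar(a$seq_fwd)
    idx <- rep.int(seq_len(nrow(a)), L)
    off <- sequence(L) - 1L
    pieces$simple <- tibble::tibble(
      read_id = a$read_id[idx],
      contig = a$contig[idx],
      pos = a$start[idx] + off,
      base = unlist(strsplit(a$seq_fwd, "", fixed = TRUE)),
      qual = unlist(phred_scores(a$qual_fwd)))
  }
  if (any(!simple)) {
    a <- aln[!simple, ]
    pieces$cigar <- purrr::pmap_dfr(
      list(a$read_id, a$contig, a$start, a$cigar, a$seq_fwd, a$qual_fwd),
      function(id, ct, st, cg, sq, ql) {
        pr <- cigar_pairs(cg, st)
        q <- utf8ToInt(ql) - 33L
        tibble::tibble(read_id = id, contig = ct, pos = pr$ref,
                       base = substring(sq, pr$read, pr$read),
                       qual = q[pr$read])
      })
  }
  dplyr::bind_rows(pieces)
}

#' Per-read allele observations at sidecar sites
#'
#' @param alignments Unique-status alignment tibble.
#' @param ref A [custom_reference()].
#' @return Tibble `read_id`, `contig`, `pos`, `base`, `qual` restricted to
#'   sidecar sites each read overlaps.
#' @export
allele_observations <- function(alignments, ref) {
  obs <- expand_alignments(alignments)
  dplyr::inner_join(obs, ref$sidecar[, c("contig", "pos")],
                    by = c("contig", "pos"))
}
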