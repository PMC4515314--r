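# Shared fixture builders and independent oracles.

random_genome <- function(len, seed, name = "chrT") {
  withr::with_seed(seed, {
    g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  })
  as_genome(setNames(g, name))
}

# Minimal unique-status alignment tibble built straight from placed sequences
# (qualities default to Q40 everywhere).
make_aln <- function(contig, start, seq_fwd, strand = "+", qual_fwd = NULL,
                     read_id = NULL) {
  n <- length(seq_fwd)
  if (is.null(qual_fwd)) qual_fwd <- strrep("I", nchar(seq_fwd))
  if (is.null(read_id)) read_id <- sprintf("t%03d", seq_len(n))
  tibble::tibble(read_id = read_id, status = "unique",
                 contig = rep_len(contig, n), start = as.integer(start),
                 strand = rep_len(strand, n), mismatches = 0L,
                 cigar = paste0(nchar(seq_fwd), "M"),
                 seq_fwd = seq_fwd, qual_fwd = qual_fwd)
}

phred_string <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)

# Brute-force reference aligner: scans every placement on every contig and
# strand, independent of the package's C++ scan.
oracle_align <- function(seq, ref, max_mismatch = 1, allele_aware = TRUE) {
  hits <- list()
  for (ct in names(ref$genome)) {
    G <- strsplit(ref$genome[[ct]], "")[[1]]
    A <- rep(".", length(G))
    sc <- ref$sidecar[ref$sidecar$contig == ct, ]
    if (nrow(sc) > 0) A[sc$pos] <- sc$alt_allele
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") seq else revcomp(seq)
      rb <- strsplit(rd, "")[[1]]
      L <- length(rb)
      if (L > length(G)) next
      for (s in seq_len(length(G) - L + 1)) {
        gb <- G[s:(s + L - 1)]
        ab <- A[s:(s + L - 1)]
        ok <- (rb == gb & rb != "N") |
          (allele_aware & ab != "." & rb == ab & rb != "N")
        mm <- sum(!ok)
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1]] <- list(ct = ct, s = s, strand = strand,
                                           mm = mm)
        }
      }
    }
  }
  if (length(hits) == 0) return(list(status = "unmapped"))
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  best <- hits[mms == min(mms)]
  if (length(best) > 1) return(list(status = "multimapped"))
  c(list(status = "unique"), best[[1]])
}

# Standard desk-scale fixture, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(.fixture_cache$std)) {
    cfg <- sim_config(seed = 20240917 %% 1e6)
    sim <- simulate_truth(cfg)
    reads <- simulate_reads(sim$genome, sim$complete, sim$truth, cfg)
    .fixture_cache$std <- list(cfg = cfg, sim = sim, reads = reads)
  }
  .fixture_cache$std
}

std_complete_run <- function() {
  if (is.null(.fixture_cache$complete_run)) {
    fx <- std_fixture()
    .fixture_cache$complete_run <-
      run_pipeline(fx$reads, fx$sim$genome, genotypes = fx$sim$complete)
  }
  .fixture_cache$complete_run
}
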