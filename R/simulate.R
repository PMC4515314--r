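#' Simulation configuration
#'
#' Defines the synthetic study conditions: a small genome sequenced at a set
#' of regulatory variant sites by a diploid sample, with controllable
#' per-site allelic ratios, sequencing errors, PCR duplicates, repeated
#' segments (to exercise multi-mapping) and partial catalog coverage.  The
#' defaults describe the package's standard desk-scale fixture: a 20 kb
#' genome with 300 variants of which 200 are heterozygous, 60 of those
#' imbalanced at a true allelic ratio of 0.8, mean depth 60 at 50 bp reads.
#'
#' @param genome_length Total genome length in bases.
#' @param n_contigs Number of contigs (length split evenly).
#' @param n_repeats,repeat_length Number and length of duplicated segments.
#' @param variant_density Variants per kb.
#' @param het_fraction Fraction of variants heterozygous in the sample.
#' @param depth Mean reads per variant site (Poisson).
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error rate; errored bases are
#'   emitted at Phred 20 so they also exercise the base-quality gate.
#' @param duplicate_rate Fraction of templates re-emitted as exact PCR
#'   copies.
#' @param imbalanced_fraction Fraction of het sites truly imbalanced.
#' @param imbalance_ratio True major-allele ratio at imbalanced sites.
#' @param partial_coverage Fraction of sample variants present in the
#'   partial catalog.
#' @param maf_range Range of the uniform alternate-allele frequency draw.
#' @param rsq_shape Shape parameters of the Beta draw for imputation
#'   quality.
#' @param seed Integer seed; fully determines all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 20000, n_contigs = 1, n_repeats = 0,
                       repeat_length = 0, variant_density = 15,
                       het_fraction = 2 / 3, depth = 60, read_length = 50,
                       error_rate = 0.005, duplicate_rate = 0.1,
                       imbalanced_fraction = 0.3, imbalance_ratio = 0.8,
                       partial_coverage = 0.8, maf_range = c(0.02, 0.98),
                       rsq_shape = c(5, 1), seed = 1) {
  cfg <- as.list(environment())
  fr <- c(cfg$het_fraction, cfg$error_rate, cfg$duplicate_rate,
          cfg$imbalanced_fraction, cfg$imbalance_ratio,
          cfg$partial_coverage)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$genome_length >= cfg$read_length)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome, variant catalogs and imbalance truth
#'
#' Generates a random genome (optionally containing duplicated segments),
#' plants biallelic SNVs at the configured density, assigns sample
#' genotypes and population frequencies, and derives the three
#' genotype-information levels: the `complete` catalog (all sample
#' genotypes), the `partial` catalog (a random `partial_coverage` subset
#' with simulated imputation quality) and the `common` catalog (variants
#' with minor allele frequency > 0.05, genotypes stripped).  The truth
#' table records each heterozygous site's true reference-allele ratio.
#'
#' @param config A [sim_config()].
#' @return A list: `genome`, `complete`, `partial`, `common`, `truth`
#'   (tibble `contig`, `pos`, `ref`, `alt`, `imbalanced`, `ratio_ref`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(cfg) {
  per_contig <- cfg$genome_length %/% cfg$n_contigs
  contig_names <- paste0("ctg", seq_len(cfg$n_contigs))
  genome <- vapply(contig_names, function(nm) {
    paste(sample(c("A", "C", "G", "T"), per_contig, replace = TRUE),
          collapse = "")
  }, character(1))

  if (cfg$n_repeats > 0 && cfg$repeat_length > 0) {
    # copy one segment of the first contig to n_repeats other places
    stopifnot(per_contig > (cfg$n_repeats + 1) * cfg$repeat_length)
    src <- sample.int(per_contig - cfg$repeat_length + 1L, 1)
    seg <- substr(genome[[1]], src, src + cfg$repeat_length - 1L)
    slots <- seq(1L, per_contig - cfg$repeat_length + 1L,
                 by = cfg$repeat_length * 2L)
    slots <- setdiff(slots, src)
    dest <- sample(slots, cfg$n_repeats)
    for (d in dest) {
      substr(genome[[1]], d, d + cfg$repeat_length - 1L) <- seg
    }
  }

  n_var <- round(cfg$genome_length / 1000 * cfg$variant_density)
  if (n_var < 1) stop("configuration yields zero variants", call. = FALSE)
  per_var <- tabulate(sample.int(cfg$n_contigs, n_var, replace = TRUE),
                      cfg$n_contigs)
  pad <- cfg$read_length
  recs <- purrr::map_dfr(seq_len(cfg$n_contigs), function(ci) {
    k <- per_var[ci]
    if (k == 0) return(NULL)
    pos <- sort(sample(seq(pad, per_contig - pad), k))
    tibble::tibble(contig = contig_names[ci], pos = pos)
  })
  recs$ref <- genome_base(genome, recs$contig, recs$pos)
  recs$alt <- vapply(other_bases(recs$ref), sample, character(1), size = 1)
  recs$af <- runif(nrow(recs), cfg$maf_range[1], cfg$maf_range[2])

  n_het <- round(nrow(recs) * cfg$het_fraction)
  het_idx <- sort(sample.int(nrow(recs), n_het))
  recs$zygosity <- "hom_ref"
  recs$zygosity[het_idx] <- "het"
  homs <- setdiff(seq_len(nrow(recs)), het_idx)
  recs$zygosity[sample(homs, floor(length(homs) / 2))] <- "hom_alt"

  complete <- variant_catalog(recs, level = "complete")

  keep <- runif(nrow(recs)) < cfg$partial_coverage
  partial_recs <- recs[keep, ]
  partial_recs$rsq <- rbeta(nrow(partial_recs), cfg$rsq_shape[1],
                            cfg$rsq_shape[2])
  partial <- variant_catalog(partial_recs, level = "partial")

  common <- derive_common_variants(complete, maf_threshold = 0.05)

  het <- recs[het_idx, ]
  n_imb <- round(nrow(het) * cfg$imbalanced_fraction)
  imb <- rep(FALSE, nrow(het))
  imb[sample.int(nrow(het), n_imb)] <- TRUE
  favored_ref <- runif(nrow(het)) < 0.5
  ratio_ref <- ifelse(!imb, 0.5,
                      ifelse(favored_ref, cfg$imbalance_ratio,
                             1 - cfg$imbalance_ratio))
  truth <- tibble::tibble(contig = het$contig, pos = het$pos, ref = het$ref,
                          alt = het$alt, imbalanced = imb,
                          ratio_ref = ratio_ref)

  list(genome = genome, complete = complete, partial = partial,
       common = common, truth = truth)
}

#' Simulate diploid reads
#'
#' Draws reads from the diploid sample implied by the genotypes: both
#' haplotypes carry the alternate allele at homozygous-alt sites, and at
#' every heterozygous site a read overlaps, the allele it carries is drawn
#' at that site's true reference-allele ratio (0.5 when balanced),
#' independently per read.  Around every catalog site, `Poisson(depth)`
#' templates are placed at uniform offsets covering the site.
#' Substitution errors are applied at `error_rate` with
#' the errored base emitted at Phred 20 (all other bases Phred 40), a
#' `duplicate_rate` fraction of templates is re-emitted as exact copies,
#' and half the reads are reverse-complemented as sequenced.
#'
#' @param genome Genome vector from [simulate_truth()].
#' @param complete The complete [variant_catalog()].
#' @param truth Truth tibble from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A read tibble (`id`, `seq`, `qual`) with attribute
#'   `n_templates` (count before PCR duplication).
#' @export
simulate_reads <- function(genome, complete, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L,
                   simulate_reads_impl(genome, complete, truth, config))
}

simulate_reads_impl <- function(genome, complete, truth, cfg) {
  rl <- cfg$read_length
  recs <- tibble::as_tibble(complete)

  # sample backbone: both haplotypes carry the alt allele at hom_alt sites
  hom_alt <- recs[recs$zygosity == "hom_alt", ]
  backbone <- set_genome_base(genome, hom_alt$contig, hom_alt$pos,
                              hom_alt$alt)

  per_site <- rpois(nrow(recs), cfg$depth)
  idx <- rep.int(seq_len(nrow(recs)), per_site)
  n_reads <- length(idx)
  if (n_reads == 0) stop("no reads simulated; increase depth", call. = FALSE)

  contig <- recs$contig[idx]
  pos <- recs$pos[idx]
  clen <- nchar(genome)[contig]
  lo <- pmax(1L, pos - rl + 1L)
  hi <- pmin(pos, clen - rl + 1L)
  start <- lo + floor(runif(n_reads) * (hi - lo + 1L))

  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    seqs[i] <- substr(backbone[[contig[i]]], start[i], start[i] + rl - 1L)
  }

  # at every heterozygous site a read overlaps, draw the allele it carries
  # at that site's true reference-allele ratio, independently per read
  rgr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, width = rl))
  tgr <- GenomicRanges::GRanges(truth$contig,
                                IRanges::IRanges(truth$pos, truth$pos))
  hits <- GenomicRanges::findOverlaps(rgr, tgr)
  ri <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  carry_ref <- runif(length(ri)) < truth$ratio_ref[ti]
  base <- ifelse(carry_ref, truth$ref[ti], truth$alt[ti])
  off <- truth$pos[ti] - start[ri] + 1L
  for (k in seq_along(ri)) {
    substr(seqs[ri[k]], off[k], off[k]) <- base[k]
  }

  # strand, then errors as sequenced
  rev <- runif(n_reads) < 0.5
  seqs[rev] <- revcomp(seqs[rev])
  quals <- rep(strrep(rawToChar(as.raw(40 + 33)), rl), n_reads)
  n_err <- rbinom(n_reads, rl, cfg$error_rate)
  err_q <- rawToChar(as.raw(20 + 33))
  for (i in which(n_err > 0)) {
    at <- sample.int(rl, n_err[i])
    for (j in at) {
      b <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      substr(quals[i], j, j) <- err_q
    }
  }

  reads <- tibble::tibble(id = sprintf("r%06d", seq_len(n_reads)),
                          seq = seqs, qual = quals)
  dup <- which(runif(n_reads) < cfg$duplicate_rate)
  if (length(dup) > 0) {
    copies <- reads[dup, ]
    copies$id <- paste0(copies$id, "dup")
    reads <- dplyr::bind_rows(reads, copies)
  }
  attr(reads, "n_templates") <- n_reads
  reads
}

#' Simulate overdispersed allele count tables
#'
#' Per site, draws `p ~ Beta(alpha, alpha)` and `n1 ~ Binomial(depth, p)`;
#' `alpha = Inf` yields pure binomial counts.  Used to exercise the
#' beta-binomial overdispersion estimator.
#'
#' @param n_sites Number of sites.
#' @param depth Reads per site.
#' @param alpha Symmetric Beta overdispersion parameter (`Inf` for none).
#' @param seed Optional integer seed.
#' @return A count tibble compatible with [estimate_alpha()].
#' @export
simulate_overdispersed_counts <- function(n_sites, depth, alpha,
                                          seed = NULL) {
  stopifnot(alpha > 0)
  gen <- function() {
    p <- if (is.finite(alpha)) rbeta(n_sites, alpha, alpha) else
      rep(0.5, n_sites)
    n1 <- rbinom(n_sites, depth, p)
    tibble::tibble(contig = "sim", pos = seq_len(n_sites), allele1 = "A",
                   allele2 = "C", n1 = n1, n2 = depth - n1, n_other = 0L,
                   site_class = "known_het")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a simulated fixture to disk
#'
#' Writes the genome (FASTA), the three catalogs (VCF), the reads (FASTQ)
#' and the truth table (TSV) under a directory, using the package's own
#' writers so everything round-trips through its readers.
#'
#' @param sim Output of [simulate_truth()].
#' @param reads Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_variant_catalog(sim$complete, file.path(dir, "complete.vcf"))
  write_variant_catalog(sim$partial, file.path(dir, "partial.vcf"))
  write_variant_catalog(sim$common, file.path(dir, "common.vcf"))
  write_fastq(reads, file.path(dir, "reads.fastq"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
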