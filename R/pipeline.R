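#' Run the allelic-imbalance pipeline end to end
#'
#' Chains reference construction, read QC, allele-aware alignment, the
#' multi-mapping/blacklist/duplicate/mappability filters, per-site allele
#' counting, heterozygous-site prediction and imbalance calling.  With
#' `second_alignment = TRUE`, predicted heterozygous sites from the first
#' round are added to the reference and alignment through calling is
#' repeated.
#'
#' The genotype regime is set by which catalogs are supplied: `common` only
#' (no genotypes), `genotypes` with level `"partial"` (Rsq-filtered before
#' use) or `"complete"`.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param genome Genome vector.
#' @param genotypes Optional genotyped [variant_catalog()].
#' @param common Optional level-`"none"` [variant_catalog()].
#' @param blacklist Optional blacklist tibble from [read_blacklist()].
#' @param max_mismatch,allele_aware Alignment options (see [align_reads()]).
#' @param rsq_threshold Strict imputation-quality cut for partial catalogs.
#' @param min_base_quality Strict base-quality gate for counting/prediction.
#' @param min_reads_per_allele,p_threshold,test,allow_complete,adjust
#'   Imbalance-calling options (see [call_imbalance()]).
#' @param trim_to,min_q,min_fraction Read-QC options (see [qc_reads()]).
#' @param predict_het Predict novel heterozygous sites; default `TRUE`.
#' @param second_alignment Run the second alignment round; default `FALSE`.
#' @return A `pipeline_result` list: `ref`, `alignments`, `counts`, `calls`
#'   (final round, with a `round` column), `predicted`, `round1` (when a
#'   second round ran) and a `manifest` of parameters and stage counters.
#' @export
run_pipeline <- function(reads, genome, genotypes = NULL, common = NULL,
                         blacklist = NULL, max_mismatch = 1,
                         allele_aware = TRUE, rsq_threshold = 0.3,
                         min_base_quality = 30, min_reads_per_allele = 5,
                         p_threshold = 0.01, test = "binomial",
                         allow_complete = FALSE, adjust = "none",
                         trim_to = NULL, min_q = 20, min_fraction = 0.9,
                         predict_het = TRUE, second_alignment = FALSE) {
  if (is.null(genotypes) && is.null(common)) {
    stop("supply at least one of 'genotypes' or 'common'", call. = FALSE)
  }

  ref <- if (!is.null(common)) build_population_reference(genome, common)
         else custom_reference(genome)
  known_class <- "common_variant"
  if (!is.null(genotypes)) {
    if (identical(catalog_level(genotypes), "partial")) {
      genotypes <- filter_by_rsq(genotypes, rsq_threshold)
    }
    ref <- customize_for_sample(ref, genotypes)
    known_class <- "known_het"
  }

  reads <- qc_reads(reads, trim_to = trim_to, min_q = min_q,
                    min_fraction = min_fraction)

  r1 <- run_alignment_round(reads, ref, blacklist, known_class,
                            max_mismatch, allele_aware, min_base_quality,
                            min_reads_per_allele, p_threshold, test,
                            allow_complete, adjust, predict_het, round = 1L)

  result <- r1
  if (second_alignment && nrow(r1$predicted) > 0) {
    ref2 <- update_reference_with_predicted(ref, r1$predicted)
    # sites added from prediction keep the predicted_het class in round 2
    pred_key <- paste(r1$predicted$contig, r1$predicted$pos)
    r2 <- run_alignment_round(reads, ref2, blacklist, known_class,
                              max_mismatch, allele_aware, min_base_quality,
                              min_reads_per_allele, p_threshold, test,
                              allow_complete, adjust, predict_het = FALSE,
                              round = 2L, predicted_keys = pred_key)
    r2$predicted <- r1$predicted
    r2$round1 <- r1
    result <- r2
  }

  result$manifest <- list(
    package = "imbalign", version = as.character(packageVersion("imbalign")),
    regime = if (!is.null(genotypes)) catalog_level(genotypes) else "none",
    parameters = list(max_mismatch = max_mismatch,
                      allele_aware = allele_aware,
                      rsq_threshold = rsq_threshold,
                      min_base_quality = min_base_quality,
                      min_reads_per_allele = min_reads_per_allele,
                      p_threshold = p_threshold, test = test,
                      allow_complete = allow_complete, adjust = adjust,
                      trim_to = trim_to, min_q = min_q,
                      min_fraction = min_fraction,
                      predict_het = predict_het,
                      second_alignment = second_alignment),
    counters = result$counters,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(result) <- "pipeline_result"
  result
}

run_alignment_round <- function(reads, ref, blacklist, known_class,
                                max_mismatch, allele_aware,
                                min_base_quality, min_reads_per_allele,
                                p_threshold, test, allow_complete, adjust,
                                predict_het, round,
                                predicted_keys = character()) {
  aln <- align_reads(reads, ref, max_mismatch = max_mismatch,
                     allele_aware = allele_aware)
  n_unique <- sum(aln$status == "unique")
  aln <- filter_alignments(aln, blacklist)
  n_after_blacklist <- nrow(aln)
  aln <- remove_duplicates(aln)
  n_after_dedup <- nrow(aln)
  aln <- mappability_filter(aln, ref, max_mismatch = max_mismatch)
  n_after_mappability <- nrow(aln)

  sc <- ref$sidecar
  sc_class <- if (length(predicted_keys) > 0) {
    ifelse(paste(sc$contig, sc$pos) %in% predicted_keys, "predicted_het",
           known_class)
  } else rep(known_class, nrow(sc))
  known_sites <- tibble::tibble(contig = sc$contig, pos = sc$pos,
                                allele1 = sc$genome_allele,
                                allele2 = sc$alt_allele,
                                site_class = sc_class)
  counts <- pileup_alleles(aln, known_sites,
                           min_base_quality = min_base_quality)

  predicted <- if (predict_het) {
    predict_het_sites(aln, ref, min_reads_per_allele = min_reads_per_allele,
                      min_base_quality = min_base_quality)
  } else {
    tibble::tibble(contig = character(), pos = integer(),
                   allele1 = character(), allele2 = character())
  }
  if (nrow(predicted) > 0) {
    pred_counts <- pileup_alleles(
      aln, dplyr::mutate(predicted, site_class = "predicted_het"),
      min_base_quality = min_base_quality)
    counts <- dplyr::bind_rows(counts, pred_counts)
  }

  calls <- call_imbalance(counts, test = test, p_threshold = p_threshold,
                          min_reads_per_allele = min_reads_per_allele,
                          allow_complete = allow_complete, adjust = adjust)
  calls$round <- round

  list(ref = ref, alignments = aln, counts = counts, calls = calls,
       predicted = predicted,
       counters = list(reads_in = nrow(reads),
                       reads_mapped_uniquely = n_unique,
                       reads_after_blacklist = n_after_blacklist,
                       reads_after_dedup = n_after_dedup,
                       reads_after_mappability = n_after_mappability,
                       sites_tested = nrow(calls),
                       sites_imbalanced = sum(calls$imbalanced)))
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  ct <- x$manifest$counters
  cat("<pipeline_result>\n")
  cat("  reads in / uniquely mapped / final: ", ct$reads_in, " / ",
      ct$reads_mapped_uniquely, " / ", ct$reads_after_mappability, "\n",
      sep = "")
  cat("  sites tested: ", ct$sites_tested, ", imbalanced: ",
      ct$sites_imbalanced, "\n", sep = "")
  invisible(x)
}

#' Re-run alignment through calling with predicted sites in the reference
#'
#' Convenience wrapper around the second round of [run_pipeline()]: updates
#' the reference with the predicted heterozygous sites of a finished first
#' round and repeats alignment, filtering, counting and calling.  With no
#' predicted sites the state is returned unchanged (round-2 calls equal
#' round-1 calls).
#'
#' @param state A `pipeline_result` from [run_pipeline()].
#' @param reads The read tibble used for the first round.
#' @param blacklist Optional blacklist tibble.
#' @return A `pipeline_result` whose `calls` carry `round = 2`.
#' @export
run_second_alignment <- function(state, reads, blacklist = NULL) {
  pars <- state$manifest$parameters
  if (nrow(state$predicted) == 0) {
    state$calls$round <- 2L
    return(state)
  }
  ref2 <- update_reference_with_predicted(state$ref, state$predicted)
  known_class <- if (state$manifest$regime == "none") "common_variant"
                 else "known_het"
  reads <- qc_reads(reads, trim_to = pars$trim_to, min_q = pars$min_q,
                    min_fraction = pars$min_fraction)
  r2 <- run_alignment_round(reads, ref2, blacklist, known_class,
                            pars$max_mismatch, pars$allele_aware,
                            pars$min_base_quality,
                            pars$min_reads_per_allele, pars$p_threshold,
                            pars$test, pars$allow_complete, pars$adjust,
                            predict_het = FALSE, round = 2L,
                            predicted_keys = paste(state$predicted$contig,
                                                   state$predicted$pos))
  r2$predicted <- state$predicted
  r2$round1 <- state
  r2$manifest <- state$manifest
  r2$manifest$counters <- r2$counters
  class(r2) <- "pipeline_result"
  r2
}
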