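#' Predict novel heterozygous sites from read evidence
#'
#' A position absent from the sidecar is predicted heterozygous when at
#' least `min_reads_per_allele` quality-passing reads carry the genome base
#' and at least as many carry one single specific other base.  The predicted
#' allele pair is the genome base and the most frequent other base (ties
#' broken alphabetically for determinism).
#'
#' @param alignments Filtered, deduplicated alignment tibble.
#' @param ref A [custom_reference()].
#' @param min_reads_per_allele Minimum reads supporting each allele;
#'   default 5.
#' @param min_base_quality Strict base-quality gate; default 30.
#' @return Tibble `contig`, `pos`, `allele1` (genome base), `allele2`.
#' @export
predict_het_sites <- function(alignments, ref, min_reads_per_allele = 5,
                              min_base_quality = 30) {
  obs <- expand_alignments(alignments)
  obs <- obs[obs$qual > min_base_quality, ]
  if (nrow(obs) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          allele1 = character(), allele2 = character()))
  }
  sc_key <- paste(ref$sidecar$contig, ref$sidecar$pos)
  obs <- obs[!paste(obs$contig, obs$pos) %in% sc_key, ]
  obs <- obs[obs$base %in% c("A", "C", "G", "T"), ]
  if (nrow(obs) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          allele1 = character(), allele2 = character()))
  }
  obs$gbase <- genome_base(ref$genome, obs$contig, obs$pos)

  per_base <- obs |>
    dplyr::count(.data$contig, .data$pos, .data$gbase, .data$base)
  ref_n <- per_base |>
    dplyr::filter(.data$base == .data$gbase) |>
    dplyr::select("contig", "pos", n_ref = "n")
  alt_n <- per_base |>
    dplyr::filter(.data$base != .data$gbase) |>
    dplyr::group_by(.data$contig, .data$pos, .data$gbase) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$base, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("contig", "pos", "gbase", alt_base = "base", n_alt = "n")

  alt_n |>
    dplyr::inner_join(ref_n, by = c("contig", "pos")) |>
    dplyr::filter(.data$n_ref >= min_reads_per_allele,
                  .data$n_alt >= min_reads_per_allele) |>
    dplyr::transmute(.data$contig, .data$pos, allele1 = .data$gbase,
                     allele2 = .data$alt_base) |>
    dplyr::arrange(.data$contig, .data$pos)
}

#' Exact two-sided binomial imbalance probability
#'
#' Computes `P(|X - n/2| >= |a1 - n/2|)` for `X ~ Binomial(n, 0.5)`, the
#' two-sided exact tail probability of observing an allele split at least as
#' extreme as `a1` out of `n` under perfectly balanced sampling (capped at
#' 1).  Under `p = 0.5` this equals doubling the smaller one-sided tail.
#'
#' @param a1 Reads carrying allele 1 (vectorized).
#' @param n Total reads at the site (`n1 + n2`).
#' @return P-values in `[0, 1]`.
#' @export
binomial_pvalue <- function(a1, n) {
  if (any(n < 1)) stop("binomial_pvalue() requires n >= 1", call. = FALSE)
  stopifnot(all(a1 >= 0), all(a1 <= n))
  mapply(function(a, nn) {
    d <- abs(a - nn / 2)
    k <- 0:nn
    min(1, sum(dbinom(k[abs(k - nn / 2) >= d], nn, 0.5)))
  }, a1, n)
}

#' Symmetric beta-binomial overdispersion model
#'
#' Fits the symmetric `Beta(alpha, alpha)`-binomial model to per-site
#' reference-allele proportions by the method of moments: `alpha` solves
#' `mean_i (2a + N_i) / (4 N_i (2a + 1)) = mean_i (p_i - 0.5)^2`, the
#' model's variance of the proportion matched to its empirical dispersion.
#' When the empirical dispersion is at or below the pure-binomial floor
#' `mean(1 / (4 N_i))`, there is no evidence of overdispersion and
#' `alpha = Inf` is returned as a sentinel.
#'
#' @param counts Count tibble with columns `n1`, `n2` (see
#'   [pileup_alleles()]).
#' @return A `bb_model` object with element `alpha`.
#' @export
estimate_alpha <- function(counts) {
  n <- counts$n1 + counts$n2
  keep <- n >= 1
  if (sum(keep) < 2) {
    stop("estimate_alpha() needs at least 2 sites with reads", call. = FALSE)
  }
  n <- n[keep]
  p <- counts$n1[keep] / n
  s2 <- mean((p - 0.5)^2)
  floor_bin <- mean(1 / (4 * n))
  if (s2 <= floor_bin) {
    return(new_bb_model(Inf, n_sites = length(n), dispersion = s2))
  }
  f <- function(a) mean((2 * a + n) / (4 * n * (2 * a + 1))) - s2
  # f is monotone decreasing in alpha from 0.25 (a -> 0) to the binomial floor
  if (f(1e-12) <= 0) return(new_bb_model(1e-12, length(n), s2))
  a_hat <- uniroot(f, interval = c(1e-12, 1e12), tol = 1e-10)$root
  new_bb_model(a_hat, n_sites = length(n), dispersion = s2)
}

new_bb_model <- function(alpha, n_sites = NA_integer_,
                         dispersion = NA_real_) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, n_sites = n_sites, dispersion = dispersion),
            class = "bb_model")
}

#' @method print bb_model
#' @export
print.bb_model <- function(x, ...) {
  cat("<bb_model> symmetric beta-binomial, alpha =",
      if (is.finite(x$alpha)) format(x$alpha, digits = 4) else
        "Inf (no overdispersion)", "\n")
  invisible(x)
}

#' @rdname estimate_alpha
#' @param x A `bb_model`.
#' @param ... Unused.
#' @export
tidy.bb_model <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha)
}

#' @rdname estimate_alpha
#' @export
glance.bb_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_sites = x$n_sites,
                 dispersion = x$dispersion,
                 overdispersed = is.finite(x$alpha))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Beta-binomial Z-statistic and p-value
#'
#' `Z = (Phat - 0.5) / sqrt((2a + N) / (4N (2a + 1)))` where `Phat = a1 / n`
#' is the proportion of reads carrying allele 1 and `N = n` the total reads
#' at the site; the p-value is the two-sided standard-normal tail of `Z`.
#' With `alpha = Inf` (no overdispersion) the denominator reduces to
#' `sqrt(1 / (4N))` and `Z` is the plain binomial z-score.
#'
#' @param a1,n Allele-1 and total read counts (vectorized).
#' @param model A `bb_model` from [estimate_alpha()].
#' @return Tibble with columns `statistic` (Z) and `p_value`.
#' @export
beta_binomial_test <- function(a1, n, model) {
  if (any(n < 1)) stop("beta_binomial_test() requires n >= 1", call. = FALSE)
  a <- model$alpha
  se <- if (is.finite(a)) sqrt((2 * a + n) / (4 * n * (2 * a + 1))) else
    sqrt(1 / (4 * n))
  z <- (a1 / n - 0.5) / se
  tibble::tibble(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Call allelic imbalance from per-site counts
#'
#' A site is tested when both alleles have at least `min_reads_per_allele`
#' supporting reads, or — with `allow_complete = TRUE` — when a known or
#' common variant has `n1 + n2 >= 2 * min_reads_per_allele` reads even if
#' one allele is absent (complete imbalance, e.g. imprinted loci).  Tested
#' sites with `p_value < p_threshold` are flagged imbalanced; all tested
#' sites are returned.  No multiple-testing correction is applied by default
#' (`adjust = "none"`), matching the uncorrected `p < 0.01` convention; set
#' `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param counts Count tibble from [pileup_alleles()].
#' @param test `"binomial"` (exact, default) or `"beta_binomial"`.
#' @param p_threshold Significance threshold; default 0.01.
#' @param min_reads_per_allele Minimum reads per allele to test; default 5.
#' @param allow_complete Also test complete imbalances at known/common
#'   sites; default `FALSE`.
#' @param model Optional `bb_model`; estimated from `counts` when needed.
#' @param adjust P-value adjustment, `"none"` or `"BH"`.
#' @return An `imbalance_calls` tibble: `contig`, `pos`, `allele1`,
#'   `allele2`, `n1`, `n2`, `p_value`, `statistic`, `favored_allele`,
#'   `test`, `site_class`, `imbalanced`.
#' @export
call_imbalance <- function(counts, test = c("binomial", "beta_binomial"),
                           p_threshold = 0.01, min_reads_per_allele = 5,
                           allow_complete = FALSE, model = NULL,
                           adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  counts <- tibble::as_tibble(counts)

  n <- counts$n1 + counts$n2
  testable <- pmin(counts$n1, counts$n2) >= min_reads_per_allele
  if (allow_complete) {
    testable <- testable |
      (counts$site_class %in% c("known_het", "common_variant") &
         n >= 2 * min_reads_per_allele)
  }
  tested <- counts[testable, ]
  if (nrow(tested) == 0) {
    out <- tibble::tibble(contig = character(), pos = integer(),
                          allele1 = character(), allele2 = character(),
                          n1 = integer(), n2 = integer(),
                          p_value = numeric(), statistic = numeric(),
                          favored_allele = character(), test = character(),
                          site_class = character(), imbalanced = logical())
    return(structure(out, class = c("imbalance_calls", class(out))))
  }
  nt <- tested$n1 + tested$n2

  if (test == "binomial") {
    p <- binomial_pvalue(tested$n1, nt)
    stat <- rep(NA_real_, nrow(tested))
  } else {
    if (is.null(model)) model <- estimate_alpha(counts)
    bb <- beta_binomial_test(tested$n1, nt, model)
    p <- bb$p_value
    stat <- bb$statistic
  }
  p_adj <- if (adjust == "BH") p.adjust(p, "BH") else p

  out <- tested |>
    dplyr::mutate(
      p_value = p, statistic = stat,
      favored_allele = dplyr::case_when(n1 > n2 ~ .data$allele1,
                                        n2 > n1 ~ .data$allele2,
                                        TRUE ~ NA_character_),
      test = .env$test,
      imbalanced = p_adj < p_threshold & .data$n1 != .data$n2) |>
    dplyr::select("contig", "pos", "allele1", "allele2", "n1", "n2",
                  "p_value", "statistic", "favored_allele", "test",
                  "site_class", "imbalanced")
  structure(out, class = c("imbalance_calls", class(out)))
}

#' Write imbalance calls and the three confidence tiers
#'
#' Writes the full call table as TSV and, when `tiers = TRUE`, the
#' three-tier outputs next to it: all calls (`*.all.tsv`), calls at known or
#' common variants (`*.known.tsv`, higher confidence) and calls at predicted
#' rare variants (`*.predicted.tsv`, lower confidence).
#'
#' @param calls An `imbalance_calls` tibble.
#' @param path Output TSV path.
#' @param tiers Also write the three-tier files; default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, tiers = FALSE) {
  readr::write_tsv(dplyr::arrange(tibble::as_tibble(calls), .data$contig,
                                  .data$pos), path)
  if (tiers) {
    stem <- sub("\\.tsv$", "", path)
    readr::write_tsv(calls, paste0(stem, ".all.tsv"))
    readr::write_tsv(calls[calls$site_class %in%
                             c("known_het", "common_variant"), ],
                     paste0(stem, ".known.tsv"))
    readr::write_tsv(calls[calls$site_class == "predicted_het", ],
                     paste0(stem, ".predicted.tsv"))
  }
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_integer(),
    allele1 = readr::col_character(), allele2 = readr::col_character(),
    n1 = readr::col_integer(), n2 = readr::col_integer(),
    p_value = readr::col_double(), statistic = readr::col_double(),
    favored_allele = readr::col_character(), test = readr::col_character(),
    site_class = readr::col_character(),
    imbalanced = readr::col_logical()))
  structure(out, class = c("imbalance_calls", class(out)))
}
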