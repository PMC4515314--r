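#' Classify calls against a truth call set
#'
#' Takes the imbalances called with complete genotype information as truth
#' and classifies the sites of a reduced-information run: `tp` — imbalanced
#' in both; `fp` — imbalanced in the calls only; `fn` — imbalanced in the
#' truth only.  Sites are matched by `(contig, pos)`; with
#' `strict_direction = TRUE` a true positive additionally requires the same
#' favored allele.
#'
#' @param calls,truth `imbalance_calls` tibbles from the evaluated and the
#'   complete-genotype run, on the same read data.
#' @param strict_direction Require favored-allele agreement for a TP.
#' @return A list of tibbles `tp`, `fp`, `fn` (columns `contig`, `pos`).
#' @export
classify_calls <- function(calls, truth, strict_direction = FALSE) {
  called <- dplyr::filter(tibble::as_tibble(calls), .data$imbalanced)
  truthy <- dplyr::filter(tibble::as_tibble(truth), .data$imbalanced)
  ck <- paste(called$contig, called$pos)
  tk <- paste(truthy$contig, truthy$pos)
  tp_keys <- intersect(ck, tk)
  if (strict_direction && length(tp_keys) > 0) {
    dir_ok <- called$favored_allele[match(tp_keys, ck)] ==
      truthy$favored_allele[match(tp_keys, tk)]
    moved <- tp_keys[!dir_ok]
    tp_keys <- tp_keys[dir_ok]
    # direction mismatches count as both a FP and a FN
    ck <- c(setdiff(ck, tk), moved)
    tk <- c(setdiff(tk, paste(called$contig, called$pos)), moved)
    return(list(tp = key_tbl(tp_keys), fp = key_tbl(ck), fn = key_tbl(tk)))
  }
  list(tp = key_tbl(tp_keys),
       fp = key_tbl(setdiff(ck, tk)),
       fn = key_tbl(setdiff(tk, ck)))
}

key_tbl <- function(keys) {
  if (length(keys) == 0) {
    return(tibble::tibble(contig = character(), pos = integer()))
  }
  parts <- stringr::str_split_fixed(keys, " ", 2)
  tibble::tibble(contig = parts[, 1], pos = as.integer(parts[, 2]))
}

#' Stratified sensitivity/precision evaluation
#'
#' Computes `sensitivity = TP / (TP + FN)` and `precision = TP / (TP + FP)`
#' overall and per site class.  Each stratum restricts both call and truth
#' imbalances to a site set: `all` (no restriction), `known_variants`
#' (sites in the run's catalog), `predicted_variants` (sites not in the
#' catalog), and `truth_restricted` (sites actually available to the run —
#' known plus tested predicted sites — the "considering only those sites"
#' comparison).  Undefined ratios (empty denominator) are `NA`.
#'
#' @inheritParams classify_calls
#' @param known_sites Tibble (`contig`, `pos`) of sites in the run's
#'   catalog/sidecar, or `NULL` to derive from `calls$site_class`.
#' @param available_sites Tibble (`contig`, `pos`) of all sites available to
#'   the run; defaults to every site in `calls` (tested sites).
#' @return An `evaluation_result` tibble: `stratum`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`.
#' @export
stratified_evaluation <- function(calls, truth, known_sites = NULL,
                                  available_sites = NULL,
                                  strict_direction = FALSE) {
  calls <- tibble::as_tibble(calls)
  truth <- tibble::as_tibble(truth)
  if (is.null(known_sites)) {
    known_sites <- calls[calls$site_class %in%
                           c("known_het", "common_variant"),
                         c("contig", "pos")]
  }
  if (is.null(available_sites)) {
    available_sites <- calls[, c("contig", "pos")]
  }
  kk <- paste(known_sites$contig, known_sites$pos)
  avail <- paste(available_sites$contig, available_sites$pos)

  strata <- list(
    all = function(k) TRUE,
    known_variants = function(k) k %in% kk,
    predicted_variants = function(k) !k %in% kk,
    truth_restricted = function(k) k %in% avail)

  out <- purrr::imap_dfr(strata, function(in_stratum, name) {
    ck <- paste(calls$contig, calls$pos)
    tk <- paste(truth$contig, truth$pos)
    cl <- classify_calls(calls[in_stratum(ck), ], truth[in_stratum(tk), ],
                         strict_direction = strict_direction)
    tp <- nrow(cl$tp); fp <- nrow(cl$fp); fn <- nrow(cl$fn)
    tibble::tibble(stratum = name, tp = tp, fp = fp, fn = fn,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  structure(out, class = c("evaluation_result", class(out)))
}

#' Read or write an evaluation report
#'
#' TSV of strata by (tp, fp, fn, sensitivity, precision).
#'
#' @param result An `evaluation_result` tibble.
#' @param path File path.
#' @return `write_evaluation()` returns `path` invisibly.
#' @export
write_evaluation <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path)
  invisible(path)
}

#' @rdname write_evaluation
#' @export
read_evaluation <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    stratum = readr::col_character(), tp = readr::col_integer(),
    fp = readr::col_integer(), fn = readr::col_integer(),
    sensitivity = readr::col_double(), precision = readr::col_double()))
  structure(out, class = c("evaluation_result", class(out)))
}
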