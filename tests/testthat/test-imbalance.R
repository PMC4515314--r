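test_that("binomial p-values match exhaustive outcome enumeration (n <= 12)", {
  # oracle: enumerate all 2^n equiprobable coin sequences
  for (n in c(1, 2, 5, 9, 12)) {
    heads <- colSums(expand.grid(rep(list(0:1), n)) |> t())
    for (a1 in 0:n) {
      extreme <- mean(abs(heads - n / 2) >= abs(a1 - n / 2))
      expect_equal(binomial_pvalue(a1, n), extreme, tolerance = 1e-12)
    }
  }
  expect_equal(binomial_pvalue(5, 10), 1)
  expect_equal(binomial_pvalue(0, 10), 2 / 1024)
  expect_error(binomial_pvalue(0, 0), "n >= 1")
})

test_that("heterozygous-site prediction needs per-allele read support", {
  g <- as_genome(c(c1 = strrep("ACGTG", 20)))
  ref <- custom_reference(g)
  site <- 50L
  gb <- genome_base(g, "c1", site)  # "G"
  mk <- function(n_ref, alt_counts) {
    # alt_counts: named vector base -> count
    seqs <- character(0)
    win <- substr(g[[1]], 41, 60)
    seqs <- rep(win, n_ref)
    for (b in names(alt_counts)) {
      s <- win
      substr(s, 10, 10) <- b
      seqs <- c(seqs, rep(s, alt_counts[[b]]))
    }
    make_aln("c1", 41L, seqs)
  }
  expect_equal(nrow(predict_het_sites(mk(5, c(T = 5)), ref)), 1)
  pred <- predict_het_sites(mk(5, c(T = 5)), ref)
  expect_equal(pred$pos, site)
  expect_equal(pred$allele1, gb)
  expect_equal(pred$allele2, "T")
  expect_equal(nrow(predict_het_sites(mk(6, c(T = 4)), ref)), 0)
  # two alternates at 3 reads each never reach the per-allele minimum
  expect_equal(nrow(predict_het_sites(mk(5, c(A = 3, T = 3)), ref)), 0)
  # sites already in the sidecar are not re-predicted
  ref2 <- custom_reference(g, tibble::tibble(contig = "c1", pos = site,
                                             genome_allele = gb,
                                             alt_allele = "T"))
  expect_equal(nrow(predict_het_sites(mk(5, c(T = 5)), ref2)), 0)
})

test_that("alpha recovery from overdispersed and binomial counts", {
  counts <- simulate_overdispersed_counts(2000, 50, alpha = 5, seed = 101)
  fit <- estimate_alpha(counts)
  expect_lt(abs(fit$alpha - 5) / 5, 0.2)

  pure <- simulate_overdispersed_counts(2000, 50, alpha = Inf, seed = 102)
  expect_equal(estimate_alpha(pure)$alpha, Inf)

  flat <- tibble::tibble(n1 = c(5L, 10L), n2 = c(5L, 10L))
  expect_equal(estimate_alpha(flat)$alpha, Inf)

  expect_error(estimate_alpha(tibble::tibble(n1 = 3L, n2 = 2L)), "2 sites")

  td <- tidy(fit)
  expect_equal(td$term, "alpha")
  expect_equal(td$estimate, fit$alpha)
  expect_true(glance(fit)$overdispersed)
})

test_that("beta-binomial Z follows the closed form and its limits", {
  z <- beta_binomial_test(9, 10, imbalign:::new_bb_model(1))
  expect_equal(round(z$statistic, 4), 1.2649)
  expect_equal(z$statistic, 0.4 / sqrt(12 / 120), tolerance = 1e-12)

  zero <- beta_binomial_test(5, 10, imbalign:::new_bb_model(1))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)

  # alpha -> Inf limit: the plain binomial z-score (Phat - 0.5) * 2 * sqrt(N)
  inf <- beta_binomial_test(c(9, 30), c(10, 40),
                            imbalign:::new_bb_model(Inf))
  expect_equal(inf$statistic,
               (c(9, 30) / c(10, 40) - 0.5) * 2 * sqrt(c(10, 40)),
               tolerance = 1e-12)
  big <- beta_binomial_test(c(9, 30), c(10, 40),
                            imbalign:::new_bb_model(1e9))
  expect_equal(big$statistic, inf$statistic, tolerance = 1e-6)

  expect_error(beta_binomial_test(0, 0, imbalign:::new_bb_model(1)),
               "n >= 1")
})

test_that("imbalance calling applies thresholds and the complete-imbalance option", {
  counts <- tibble::tibble(
    contig = "c1", pos = c(10L, 20L, 30L),
    allele1 = "A", allele2 = "G",
    n1 = c(27L, 4L, 0L), n2 = c(6L, 100L, 20L), n_other = 0L,
    site_class = c("known_het", "known_het", "known_het"))

  calls <- call_imbalance(counts)
  expect_equal(nrow(calls), 1)            # only 27/6 passes min reads
  expect_true(calls$imbalanced)
  expect_equal(calls$favored_allele, "A")
  expect_equal(calls$p_value, binomial_pvalue(27, 33))

  # allow_complete opens testing for any known site with enough total reads,
  # including one-allele-only (complete) imbalances like 0/20
  with_complete <- call_imbalance(counts, allow_complete = TRUE)
  expect_equal(sort(with_complete$pos), c(10L, 20L, 30L))
  expect_true(with_complete$imbalanced[with_complete$pos == 30L])
  expect_equal(with_complete$favored_allele[with_complete$pos == 30L], "G")

  # the relaxation never applies at predicted sites
  counts$site_class[3] <- "predicted_het"
  expect_equal(sort(call_imbalance(counts, allow_complete = TRUE)$pos),
               c(10L, 20L))

  expect_error(call_imbalance(counts, test = "chi"), "arg")
})

test_that("raising the per-allele minimum never adds tested sites", {
  withr::local_seed(17)
  counts <- tibble::tibble(contig = "c1", pos = seq_len(200),
                           allele1 = "A", allele2 = "G",
                           n1 = rbinom(200, 40, 0.5)) |>
    dplyr::mutate(n2 = 40L - n1, n_other = 0L, site_class = "known_het")
  tested <- vapply(1:12, function(m) {
    nrow(call_imbalance(counts, min_reads_per_allele = m))
  }, numeric(1))
  expect_true(all(diff(tested) <= 0))
})

test_that("beta-binomial calling is more conservative on overdispersed nulls", {
  counts <- simulate_overdispersed_counts(3000, 50, alpha = 2, seed = 77)
  bin <- call_imbalance(counts, test = "binomial")
  bb <- call_imbalance(counts, test = "beta_binomial")
  expect_lt(sum(bb$imbalanced), sum(bin$imbalanced))
  expect_false(anyNA(bb$statistic))
})

test_that("calls round-trip through the TSV writer with confidence tiers", {
  counts <- tibble::tibble(contig = "c1", pos = c(10L, 20L),
                           allele1 = "A", allele2 = "G",
                           n1 = c(27L, 8L), n2 = c(6L, 9L), n_other = 0L,
                           site_class = c("known_het", "predicted_het"))
  calls <- call_imbalance(counts)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f, tiers = TRUE)
  back <- read_calls(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(calls))
  stem <- sub("\\.tsv$", "", f)
  known <- readr::read_tsv(paste0(stem, ".known.tsv"),
                           show_col_types = FALSE)
  pred <- readr::read_tsv(paste0(stem, ".predicted.tsv"),
                          show_col_types = FALSE)
  expect_equal(known$pos, 10)
  expect_equal(pred$pos, 20)
})
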