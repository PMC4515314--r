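test_that("population reference substitutes major alleles and records minors", {
  g <- as_genome(c(c1 = "AAAAAAAAAA"))
  common <- variant_catalog(tibble::tibble(
    contig = "c1", pos = c(3L, 6L), ref = "A", alt = "G",
    af = c(0.7, 0.1)), "none")
  ref <- build_population_reference(g, common)
  expect_equal(ref$genome[["c1"]], "AAGAAAAAAA")
  expect_equal(ref$sidecar$genome_allele, c("G", "A"))
  expect_equal(ref$sidecar$alt_allele, c("A", "G"))

  # exact 0.5 tie keeps the original reference base
  tie <- variant_catalog(tibble::tibble(contig = "c1", pos = 3L, ref = "A",
                                        alt = "G", af = 0.5), "none")
  expect_equal(build_population_reference(g, tie)$genome[["c1"]], g[["c1"]])

  empty <- variant_catalog(tibble::tibble(contig = character(),
                                          pos = integer(), ref = character(),
                                          alt = character(),
                                          af = numeric()), "none")
  ref0 <- build_population_reference(g, empty)
  expect_equal(ref0$genome, g)
  expect_equal(nrow(ref0$sidecar), 0)

  bad <- variant_catalog(tibble::tibble(contig = "c1", pos = 3L, ref = "C",
                                        alt = "G", af = 0.7), "none")
  expect_error(build_population_reference(g, bad), "c1:3")
})

test_that("sample customization places het alleles across genome and sidecar", {
  g <- as_genome(c(c1 = "ACGTACGTAC"))
  gts <- variant_catalog(tibble::tibble(
    contig = "c1", pos = c(2L, 5L, 8L), ref = c("C", "A", "T"),
    alt = c("G", "G", "C"),
    zygosity = c("het", "hom_alt", "hom_ref")), "complete")
  ref <- customize_for_sample(custom_reference(g), gts)
  expect_equal(ref$genome[["c1"]], "ACGTGCGTAC")
  expect_equal(nrow(ref$sidecar), 1)
  expect_equal(ref$sidecar$pos, 2L)
  expect_equal(ref$sidecar$genome_allele, "C")
  expect_equal(ref$sidecar$alt_allele, "G")

  # stale sidecar entries at now-homozygous sites are removed; a het site
  # whose population genome base is the alt allele keeps it in the genome
  pop <- custom_reference(
    as_genome(c(c1 = "AGGTACGTAC")),
    tibble::tibble(contig = "c1", pos = c(2L, 8L),
                   genome_allele = c("G", "T"), alt_allele = c("C", "C")))
  ref2 <- customize_for_sample(pop, gts)
  expect_equal(substr(ref2$genome[["c1"]], 8, 8), "T")
  expect_false(8L %in% ref2$sidecar$pos)
  expect_equal(ref2$sidecar$genome_allele[ref2$sidecar$pos == 2L], "G")
  expect_equal(ref2$sidecar$alt_allele[ref2$sidecar$pos == 2L], "C")
})

test_that("for every het site exactly one sample allele is in the genome", {
  withr::local_seed(5)
  for (rep in 1:5) {
    g <- random_genome(300, seed = rep, name = "cx")
    n <- 20
    pos <- sort(sample(10:290, n))
    ref_al <- genome_base(g, "cx", pos)
    alt_al <- purrr::map_chr(ref_al,
                             ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
    gts <- variant_catalog(tibble::tibble(
      contig = "cx", pos = pos, ref = ref_al, alt = alt_al,
      af = runif(n),
      zygosity = sample(c("het", "hom_ref", "hom_alt"), n, TRUE)),
      "complete")
    pop <- build_population_reference(g, derive_common_variants(gts, 0.05))
    ref <- customize_for_sample(pop, gts)
    het <- gts[gts$zygosity == "het", ]
    gb <- genome_base(ref$genome, het$contig, het$pos)
    sb <- ref$sidecar$alt_allele[match(paste(het$contig, het$pos),
                                       paste(ref$sidecar$contig,
                                             ref$sidecar$pos))]
    expect_true(all(sort(c(gb, sb)) == sort(c(het$ref, het$alt))))
    expect_true(all((gb == het$ref & sb == het$alt) |
                      (gb == het$alt & sb == het$ref)))
    # contig lengths preserved by every construction step
    expect_equal(nchar(ref$genome), nchar(g))
  }
})

test_that("the complement reference swaps alleles and is an involution", {
  g <- as_genome(c(c1 = "AAAAAAAAAA"))
  ref <- custom_reference(g, tibble::tibble(contig = "c1", pos = 4L,
                                            genome_allele = "A",
                                            alt_allele = "G"))
  comp <- build_complement_reference(ref)
  expect_equal(substr(comp$genome[["c1"]], 4, 4), "G")
  expect_equal(comp$sidecar$alt_allele, "A")
  back <- build_complement_reference(comp)
  expect_identical(back$genome, ref$genome)
  expect_identical(back$sidecar, ref$sidecar)

  no_sc <- custom_reference(g)
  expect_identical(build_complement_reference(no_sc)$genome, g)
})

test_that("predicted het sites extend the sidecar per the update rules", {
  g <- as_genome(c(c1 = "CCCCCGCCCC"))
  ref <- custom_reference(g)
  upd <- update_reference_with_predicted(
    ref, tibble::tibble(contig = "c1", pos = 2L, allele1 = "C",
                        allele2 = "T"))
  expect_equal(upd$genome[["c1"]], g[["c1"]])
  expect_equal(upd$sidecar$alt_allele, "T")

  # genome base matching neither predicted allele is overwritten by allele1
  upd2 <- update_reference_with_predicted(
    ref, tibble::tibble(contig = "c1", pos = 6L, allele1 = "C",
                        allele2 = "T"))
  expect_equal(substr(upd2$genome[["c1"]], 6, 6), "C")
  expect_equal(upd2$sidecar$alt_allele, "T")

  expect_identical(update_reference_with_predicted(ref, tibble::tibble(
    contig = character(), pos = integer(), allele1 = character(),
    allele2 = character())), ref)

  # conflicting entry at an existing sidecar site: kept, with a warning
  ref2 <- custom_reference(g, tibble::tibble(contig = "c1", pos = 6L,
                                             genome_allele = "G",
                                             alt_allele = "A"))
  expect_warning(
    upd3 <- update_reference_with_predicted(
      ref2, tibble::tibble(contig = "c1", pos = 6L, allele1 = "G",
                           allele2 = "T")),
    "conflict")
  expect_equal(upd3$sidecar$alt_allele, "A")
})

test_that("FASTA and sidecar writers round-trip through their readers", {
  g <- random_genome(150, seed = 9, name = "scaffold_1")
  ref <- custom_reference(g, tibble::tibble(contig = "scaffold_1",
                                            pos = c(10L, 99L),
                                            genome_allele = genome_base(
                                              g, "scaffold_1", c(10L, 99L)),
                                            alt_allele = c("N", "N")) |>
                            dplyr::mutate(alt_allele = purrr::map_chr(
                              genome_allele,
                              ~ setdiff(c("A", "C", "G", "T"), .x)[1])))
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genome(ref$genome, fa)
  write_sidecar(ref, tsv)
  expect_identical(read_genome(fa), ref$genome)
  expect_identical(read_sidecar(tsv), ref$sidecar)
})
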