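test_that("exact, ambiguous and failed placements are classified", {
  g <- random_genome(400, seed = 1)
  ref <- custom_reference(g)
  read30 <- substr(g[[1]], 101, 130)
  reads <- tibble::tibble(
    id = c("exact", "rc", "nohit"),
    seq = c(read30, revcomp(substr(g[[1]], 201, 230)), strrep("A", 30)),
    qual = strrep("I", 30))
  aln <- align_reads(reads, ref, max_mismatch = 0)
  expect_equal(aln$status, c("unique", "unique", "unmapped"))
  expect_equal(aln$start[1:2], c(101L, 201L))
  expect_equal(aln$strand[1:2], c("+", "-"))
  expect_equal(aln$mismatches[1:2], c(0L, 0L))
  # minus-strand sequence reported in forward orientation
  expect_equal(aln$seq_fwd[2], substr(g[[1]], 201, 230))

  # identical repeat copies make a read ambiguous
  rep_g <- as_genome(c(r = paste0(read30, strrep("T", 40), read30)))
  aln2 <- align_reads(reads[1, ], custom_reference(rep_g), max_mismatch = 0)
  expect_equal(aln2$status, "multimapped")
})

test_that("allele-aware placement rescues reads carrying the sidecar allele", {
  g <- random_genome(300, seed = 2)
  pos <- 150L
  gb <- genome_base(g, names(g), pos)
  ab <- setdiff(c("A", "C", "G", "T"), gb)[1]
  ref <- custom_reference(g, tibble::tibble(contig = names(g), pos = pos,
                                            genome_allele = gb,
                                            alt_allele = ab))
  alt_read <- substr(g[[1]], 131, 170)
  substr(alt_read, 20, 20) <- ab
  reads <- tibble::tibble(id = "alt", seq = alt_read, qual = strrep("I", 40))

  aware <- align_reads(reads, ref, max_mismatch = 0, allele_aware = TRUE)
  expect_equal(aware$status, "unique")
  expect_equal(aware$mismatches, 0L)
  blind <- align_reads(reads, ref, max_mismatch = 0, allele_aware = FALSE)
  expect_equal(blind$status, "unmapped")
})

test_that("the scan agrees with a brute-force oracle on random reads", {
  withr::local_seed(42)
  g <- random_genome(600, seed = 3)
  pos <- sort(sample(50:550, 6))
  gb <- genome_base(g, names(g), pos)
  ab <- purrr::map_chr(gb, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
  ref <- custom_reference(g, tibble::tibble(contig = names(g), pos = pos,
                                            genome_allele = gb,
                                            alt_allele = ab))
  for (i in 1:40) {
    s <- sample(1:560, 1)
    rd <- substr(g[[1]], s, s + 39)
    n_mut <- sample(0:2, 1)
    for (j in sample(1:40, n_mut)) {
      substr(rd, j, j) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.5) rd <- revcomp(rd)
    mm_budget <- sample(0:2, 1)
    aware <- runif(1) < 0.5
    got <- align_reads(tibble::tibble(id = "x", seq = rd,
                                      qual = strrep("I", 40)),
                       ref, max_mismatch = mm_budget, allele_aware = aware)
    want <- oracle_align(rd, ref, max_mismatch = mm_budget,
                         allele_aware = aware)
    expect_equal(got$status, want$status)
    if (want$status == "unique") {
      expect_equal(got$start, want$s)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("SAM output round-trips through ingestion", {
  g <- random_genome(500, seed = 4)
  ref <- custom_reference(g)
  withr::local_seed(7)
  starts <- sample(1:460, 20)
  reads <- tibble::tibble(
    id = sprintf("rd%02d", 1:20),
    seq = substring(g[[1]], starts, starts + 39),
    qual = strrep("I", 40))
  reads$seq[1:5] <- revcomp(reads$seq[1:5])
  aln <- align_reads(reads, ref, max_mismatch = 0)
  expect_true(all(aln$status == "unique"))

  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, ref, f)
  back <- ingest_sam(f, ref)
  key <- function(x) dplyr::arrange(
    x[, c("read_id", "contig", "start", "strand", "mismatches", "seq_fwd",
          "qual_fwd")], read_id)
  expect_equal(key(back), key(aln))
})

test_that("SAM flags map to alignment status", {
  g <- as_genome(c(chrS = strrep("ACGT", 30)))
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:chrS\tLN:120",
           "r1\t0\tchrS\t5\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII\tNM:i:0",
           "r2\t256\tchrS\t5\t0\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII\tNM:i:0",
           "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGT\tIIIIIIII")
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  got <- ingest_sam(f, custom_reference(g))
  expect_equal(sort(got$status), c("multimapped", "unique", "unmapped"))
  expect_equal(got$status[got$read_id == "r2"][1], "multimapped")

  empty <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrS\tLN:120"), empty)
  expect_equal(nrow(ingest_sam(empty, custom_reference(g))), 0)
})

test_that("cigar-aware expansion skips inserted and clipped bases", {
  aln <- tibble::tibble(read_id = "c1", status = "unique", contig = "chrS",
                        start = 10L, strand = "+", mismatches = 0L,
                        cigar = "3M2I2M2D3M",
                        seq_fwd = "AAACCGGTTT",
                        qual_fwd = strrep("I", 10))
  obs <- imbalign:::expand_alignments(aln)
  expect_equal(nrow(obs), 8)   # 3 + 2 + 3 aligned bases
  expect_equal(obs$pos, c(10:12, 13:14, 17:19))
  expect_equal(obs$base, c("A", "A", "A", "G", "G", "T", "T", "T"))
})

test_that("blacklist and multimapper filtering follow the interval rules", {
  aln <- dplyr::bind_rows(
    make_aln("c1", 100L, strrep("A", 20), read_id = "in_bl"),
    make_aln("c1", 300L, strrep("A", 20), read_id = "clear"))
  multi <- tibble::tibble(read_id = "mm", status = "multimapped",
                          contig = NA, start = NA_integer_,
                          strand = NA_character_, mismatches = 1L,
                          cigar = NA_character_, seq_fwd = NA_character_,
                          qual_fwd = NA_character_)
  bl <- tibble::tibble(contig = "c1", start = 110L, end = 150L)
  kept <- filter_alignments(dplyr::bind_rows(aln, multi), bl)
  expect_equal(kept$read_id, "clear")
  # empty blacklist still removes non-unique records
  expect_equal(filter_alignments(dplyr::bind_rows(aln, multi))$read_id,
               c("in_bl", "clear"))
})

test_that("duplicate removal keys on contig, 5' position and strand", {
  trio <- make_aln("c1", 50L, rep(strrep("G", 10), 3),
                   qual_fwd = c(phred_string(40, 10), phred_string(30, 10),
                                phred_string(40, 10)),
                   read_id = c("b", "c", "a"))
  kept <- remove_duplicates(trio)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$read_id, "a")  # highest quality, then smallest id

  # opposite strands at the same position are distinct templates
  pair <- make_aln("c1", 50L, rep(strrep("G", 10), 2), strand = c("+", "-"),
                   read_id = c("p", "q"))
  expect_equal(nrow(remove_duplicates(pair)), 2)

  # minus-strand 5' end is the rightmost base: same end, different starts
  minus <- make_aln("c1", c(41L, 46L), c(strrep("G", 20), strrep("G", 15)),
                    strand = "-", read_id = c("u", "v"))
  expect_equal(nrow(remove_duplicates(minus)), 1)

  once <- remove_duplicates(trio)
  expect_identical(remove_duplicates(once), once)
})
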