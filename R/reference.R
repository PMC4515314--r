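#' Custom references with an alternate-allele sidecar
#'
#' A custom reference pairs a genome with a *sidecar* table of alternate
#' alleles: one row per site where two alleles should be treated as equal
#' matches during allele-aware alignment.  The genome carries one allele at
#' each such site and the sidecar the other, analogous to the SNP file fed to
#' an allele-aware aligner.
#'
#' @param genome Genome vector (see [as_genome()]).
#' @param sidecar Tibble with columns `contig`, `pos` (1-based),
#'   `genome_allele`, `alt_allele`; defaults to empty.
#' @return A `custom_ref` object (list with `genome` and `sidecar`).
#' @export
custom_reference <- function(genome, sidecar = empty_sidecar()) {
  genome <- as_genome(genome)
  sidecar <- tibble::as_tibble(sidecar)
  sidecar <- sidecar[, c("contig", "pos", "genome_allele", "alt_allele")]
  sidecar$pos <- as.integer(sidecar$pos)
  sidecar <- dplyr::arrange(sidecar, match(.data$contig, names(genome)),
                            .data$pos)
  if (nrow(sidecar) > 0) {
    gb <- genome_base(genome, sidecar$contig, sidecar$pos)
    if (any(gb != sidecar$genome_allele)) {
      i <- which(gb != sidecar$genome_allele)[1]
      stop("sidecar genome_allele disagrees with genome at ",
           sidecar$contig[i], ":", sidecar$pos[i], call. = FALSE)
    }
    if (any(sidecar$genome_allele == sidecar$alt_allele)) {
      stop("sidecar alternate allele equals the genome allele", call. = FALSE)
    }
    if (anyDuplicated(paste(sidecar$contig, sidecar$pos)) > 0) {
      stop("duplicate sidecar site", call. = FALSE)
    }
  }
  structure(list(genome = genome, sidecar = sidecar), class = "custom_ref")
}

empty_sidecar <- function() {
  tibble::tibble(contig = character(), pos = integer(),
                 genome_allele = character(), alt_allele = character())
}

#' @method print custom_ref
#' @export
print.custom_ref <- function(x, ...) {
  cat("<custom_ref> ", length(x$genome), " contig(s), ",
      sum(nchar(x$genome)), " bp, ", nrow(x$sidecar),
      " sidecar site(s)\n", sep = "")
  invisible(x)
}

#' Build the population major-allele reference
#'
#' At every common variant the genome base is replaced by the population
#' major allele (the allele with frequency > 0.5; an exact 0.5/0.5 tie keeps
#' the original reference base) and the minor allele is recorded in the
#' sidecar, so that alignment treats both alleles equally for any sample.
#'
#' @param genome Genome vector.
#' @param common A level-`"none"` [variant_catalog()] with `af` present.
#' @return A [custom_reference()].
#' @export
build_population_reference <- function(genome, common) {
  genome <- as_genome(genome)
  if (!identical(catalog_level(common), "none")) {
    stop("build_population_reference() expects a level 'none' catalog",
         call. = FALSE)
  }
  if (nrow(common) == 0) return(custom_reference(genome))
  gb <- genome_base(genome, common$contig, common$pos)
  if (any(gb != common$ref)) {
    i <- which(gb != common$ref)[1]
    stop("catalog/genome mismatch at ", common$contig[i], ":", common$pos[i],
         ": catalog ref ", common$ref[i], ", genome base ", gb[i],
         call. = FALSE)
  }
  major <- ifelse(common$af > 0.5, common$alt, common$ref)
  minor <- ifelse(common$af > 0.5, common$ref, common$alt)
  genome <- set_genome_base(genome, common$contig, common$pos, major)
  custom_reference(genome,
                   tibble::tibble(contig = common$contig, pos = common$pos,
                                  genome_allele = major, alt_allele = minor))
}

#' Customize a reference with sample genotypes
#'
#' Homozygous sites get the sample allele in the genome and leave the sidecar
#' (no alternate exists in this sample); heterozygous sites get one sample
#' allele in the genome and the other in the sidecar.  When the current
#' genome base is already one of the two heterozygous alleles it is kept
#' (deterministic, and keeps complete/partial runs comparable).  Sites absent
#' from `genotypes` retain their population-reference state.
#'
#' @param ref A [custom_reference()].
#' @param genotypes A level-`"complete"` or `"partial"` [variant_catalog()].
#' @return A [custom_reference()].
#' @export
customize_for_sample <- function(ref, genotypes) {
  if (!catalog_level(genotypes) %in% c("complete", "partial")) {
    stop("customize_for_sample() requires a genotyped catalog", call. = FALSE)
  }
  genome <- ref$genome
  sidecar <- ref$sidecar
  gt <- tibble::as_tibble(genotypes)
  gt <- gt[gt$zygosity != "unknown", ]
  if (nrow(gt) == 0) return(custom_reference(genome, sidecar))

  gt$key <- paste(gt$contig, gt$pos)
  sidecar_key <- paste(sidecar$contig, sidecar$pos)

  hom <- gt[gt$zygosity != "het", ]
  if (nrow(hom) > 0) {
    allele <- ifelse(hom$zygosity == "hom_alt", hom$alt, hom$ref)
    genome <- set_genome_base(genome, hom$contig, hom$pos, allele)
    sidecar <- sidecar[!sidecar_key %in% hom$key, ]
    sidecar_key <- paste(sidecar$contig, sidecar$pos)
  }

  het <- gt[gt$zygosity == "het", ]
  if (nrow(het) > 0) {
    cur <- genome_base(genome, het$contig, het$pos)
    in_genome <- ifelse(cur == het$alt, het$alt, het$ref)
    in_sidecar <- ifelse(cur == het$alt, het$ref, het$alt)
    genome <- set_genome_base(genome, het$contig, het$pos, in_genome)
    sidecar <- sidecar[!sidecar_key %in% het$key, ]
    sidecar <- dplyr::bind_rows(sidecar,
                                tibble::tibble(contig = het$contig,
                                               pos = het$pos,
                                               genome_allele = in_genome,
                                               alt_allele = in_sidecar))
  }
  custom_reference(genome, sidecar)
}

#' Build the complement reference
#'
#' Exchanges the genome and sidecar allele at every sidecar site, leaving all
#' other bases untouched.  Aligning the same reads allele-aware to a
#' reference and to its complement should give identical placements; the
#' operation is an involution used to verify that both alleles are treated
#' symmetrically.
#'
#' @param ref A [custom_reference()].
#' @return A [custom_reference()].
#' @export
build_complement_reference <- function(ref) {
  sc <- ref$sidecar
  if (nrow(sc) == 0) return(ref)
  genome <- set_genome_base(ref$genome, sc$contig, sc$pos, sc$alt_allele)
  custom_reference(genome,
                   tibble::tibble(contig = sc$contig, pos = sc$pos,
                                  genome_allele = sc$alt_allele,
                                  alt_allele = sc$genome_allele))
}

#' Add predicted heterozygous sites to a reference
#'
#' Before a second alignment round, each predicted heterozygous site is added
#' to the sidecar: if the current genome base is one of the two predicted
#' alleles it is kept and the other goes to the sidecar, otherwise the genome
#' is set to `allele1` and the sidecar to `allele2`.  Sites already in the
#' sidecar are kept as they are (with a warning if the allele pair differs).
#'
#' @param ref A [custom_reference()].
#' @param predicted Tibble with columns `contig`, `pos`, `allele1`, `allele2`
#'   (as returned by [predict_het_sites()]).
#' @return A [custom_reference()].
#' @export
update_reference_with_predicted <- function(ref, predicted) {
  predicted <- tibble::as_tibble(predicted)
  if (nrow(predicted) == 0) return(ref)
  stopifnot(all(c("contig", "pos", "allele1", "allele2") %in% names(predicted)))
  sc_key <- paste(ref$sidecar$contig, ref$sidecar$pos)
  pr_key <- paste(predicted$contig, predicted$pos)

  existing <- predicted[pr_key %in% sc_key, ]
  if (nrow(existing) > 0) {
    sc <- ref$sidecar[match(paste(existing$contig, existing$pos), sc_key), ]
    differs <- !((sc$genome_allele == existing$allele1 &
                    sc$alt_allele == existing$allele2) |
                   (sc$genome_allele == existing$allele2 &
                      sc$alt_allele == existing$allele1))
    if (any(differs)) {
      warning("predicted alleles at ", sum(differs),
              " site(s) conflict with existing sidecar entries; keeping the ",
              "existing entries", call. = FALSE)
    }
  }

  new <- predicted[!pr_key %in% sc_key, ]
  if (nrow(new) == 0) return(ref)
  cur <- genome_base(ref$genome, new$contig, new$pos)
  in_genome <- dplyr::case_when(cur == new$allele1 ~ new$allele1,
                                cur == new$allele2 ~ new$allele2,
                                TRUE ~ new$allele1)
  in_sidecar <- ifelse(in_genome == new$allele1, new$allele2, new$allele1)
  genome <- set_genome_base(ref$genome, new$contig, new$pos, in_genome)
  custom_reference(genome,
                   dplyr::bind_rows(ref$sidecar,
                                    tibble::tibble(contig = new$contig,
                                                   pos = new$pos,
                                                   genome_allele = in_genome,
                                                   alt_allele = in_sidecar)))
}

#' Read or write a sidecar table
#'
#' The sidecar serializes as a TSV with columns
#' `contig  pos  genome_allele  alt_allele` (1-based positions, sorted by
#' contig then position).
#'
#' @param ref A [custom_reference()] (for writing).
#' @param path File path.
#' @return `write_sidecar()` returns `path` invisibly; `read_sidecar()` the
#'   sidecar tibble.
#' @export
write_sidecar <- function(ref, path) {
  readr::write_tsv(ref$sidecar, path)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_integer(),
    genome_allele = readr::col_character(),
    alt_allele = readr::col_character()))
}
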