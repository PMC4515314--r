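#' Variant catalogs
#'
#' A variant catalog is a tibble of biallelic SNVs with one row per
#' `(contig, pos)` and an information `level` attribute describing how much
#' genotype information it carries:
#'
#' * `"complete"` — sequencing-based sample genotypes,
#' * `"partial"` — imputed array genotypes with an imputation quality (`rsq`),
#' * `"none"` — population common variants only (genotypes unknown).
#'
#' Columns: `contig`, `pos` (1-based), `ref`, `alt` (single bases), `af`
#' (alternate-allele population frequency, may be `NA`), `maf`
#' (`pmin(af, 1 - af)`), `rsq` (imputation quality, may be `NA`) and
#' `zygosity` (`hom_ref`, `het`, `hom_alt` or `unknown`).
#'
#' @param records Data frame with the columns above (`af`, `rsq` optional).
#' @param level Information level, one of `"complete"`, `"partial"`, `"none"`.
#' @return A `variant_catalog` tibble.
#' @export
variant_catalog <- function(records, level = c("complete", "partial", "none")) {
  level <- match.arg(level)
  records <- tibble::as_tibble(records)
  if (!"af" %in% names(records)) records$af <- NA_real_
  if (!"rsq" %in% names(records)) records$rsq <- NA_real_
  if (!"zygosity" %in% names(records)) records$zygosity <- "unknown"
  records$maf <- pmin(records$af, 1 - records$af)
  records <- records[, c("contig", "pos", "ref", "alt", "af", "maf", "rsq",
                         "zygosity")]
  records$pos <- as.integer(records$pos)

  validate_catalog(records, level)
  structure(records, level = level,
            class = c("variant_catalog", class(tibble::tibble())))
}

validate_catalog <- function(records, level) {
  with(records, {
    if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
      stop("catalog records must be single-nucleotide variants", call. = FALSE)
    }
    if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
    if (!all(zygosity %in% c("hom_ref", "het", "hom_alt", "unknown"))) {
      stop("invalid zygosity value", call. = FALSE)
    }
  })
  key <- paste(records$contig, records$pos)
  if (anyDuplicated(key) > 0) {
    stop("duplicate variant record at ", key[duplicated(key)][1], call. = FALSE)
  }
  if (level == "none") {
    if (!all(records$zygosity == "unknown")) {
      stop("a level 'none' catalog cannot carry genotypes", call. = FALSE)
    }
    if (anyNA(records$maf)) {
      stop("a level 'none' catalog requires maf on every record", call. = FALSE)
    }
  }
  invisible(records)
}

#' @rdname variant_catalog
#' @param x Object to query.
#' @export
catalog_level <- function(x) attr(x, "level")

#' Read a variant catalog from a VCF file
#'
#' Parses a single-sample VCF 4.x subset: `CHROM`, `POS`, `REF`, `ALT`,
#' `INFO/AF`, `INFO/RSQ` (or `R2`) and `FORMAT/GT`.  Multiallelic records and
#' indels are skipped; the number skipped is reported as a message and stored
#' in the `n_skipped` attribute.  Unknown INFO keys are ignored.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @inheritParams variant_catalog
#' @return A [variant_catalog()] tibble.
#' @export
read_variant_catalog <- function(path, level = c("complete", "partial", "none")) {
  level <- match.arg(level)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = as.integer(length(fix) > 0),
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(variant_catalog(tibble::tibble(contig = character(), pos = integer(),
                                          ref = character(), alt = character()),
                           level = level))
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad) > 0) {
    stop("malformed VCF record ", bad[1], " (", fix[bad[1], "CHROM"], ":",
         fix[bad[1], "POS"], ")", call. = FALSE)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " multiallelic/indel record(s)")
  }

  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
  rsq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "RSQ")))
  if (all(is.na(rsq))) {
    rsq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "R2")))
  }

  zyg <- rep("unknown", n)
  if (level != "none") {
    gt <- tryCatch(vcfR::extract.gt(vcf, "GT"), error = function(e) NULL)
    if (is.null(gt)) stop("level '", level, "' requires a FORMAT/GT field",
                          call. = FALSE)
    zyg <- gt_to_zygosity(gt[, 1])
  }

  out <- tibble::tibble(contig = fix[, "CHROM"], pos = pos, ref = ref,
                        alt = alt, af = af, rsq = rsq, zygosity = zyg)[keep, ]
  cat_out <- variant_catalog(out, level = level)
  attr(cat_out, "n_skipped") <- n_skipped
  cat_out
}

gt_to_zygosity <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  z <- dplyr::case_when(
    is.na(gt) | gt %in% c(".", "./.") ~ "unknown",
    gt == "0/0" ~ "hom_ref",
    gt %in% c("0/1", "1/0") ~ "het",
    gt == "1/1" ~ "hom_alt",
    TRUE ~ NA_character_
  )
  if (anyNA(z)) stop("unrecognized GT value '", gt[is.na(z)][1], "'",
                     call. = FALSE)
  z
}

#' Write a variant catalog as VCF
#'
#' Deterministic single-sample VCF writer (records sorted by contig then
#' position).  `AF` and `RSQ` go to INFO; genotypes to a single `FORMAT/GT`
#' sample column unless the catalog level is `"none"`.
#'
#' @param catalog A [variant_catalog()].
#' @param path Output path.
#' @param sample_name Sample column name for genotyped catalogs.
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(catalog, path, sample_name = "SAMPLE") {
  level <- catalog_level(catalog)
  df <- dplyr::arrange(tibble::as_tibble(catalog), .data$contig, .data$pos)

  info <- purrr::map2_chr(df$af, df$rsq, function(af, rsq) {
    # %.17g survives a write/read cycle bit-exactly for doubles
    parts <- c(if (!is.na(af)) sprintf("AF=%.17g", af),
               if (!is.na(rsq)) sprintf("RSQ=%.17g", rsq))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  })

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(df$contig), ">"),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality\">"
  )
  if (level == "none") {
    cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO"), collapse = "\t")
    body <- paste(df$contig, df$pos, ".", df$ref, df$alt, ".", ".", info,
                  sep = "\t")
  } else {
    header <- c(header,
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample_name), collapse = "\t")
    gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
            unknown = "./.")[df$zygosity]
    body <- paste(df$contig, df$pos, ".", df$ref, df$alt, ".", ".", info,
                  "GT", gt, sep = "\t")
  }
  writeLines(c(header, cols, body), path)
  invisible(path)
}

#' Filter a partial catalog by imputation quality
#'
#' Retains records whose imputation quality satisfies `rsq > threshold`
#' (strict, mirroring the pipeline's `Rsq > 0.3` default); records with no
#' `rsq` are dropped.
#'
#' @param catalog A level-`"partial"` [variant_catalog()].
#' @param threshold Strict lower bound in `[0, 1]`; default 0.3.
#' @return The filtered catalog.
#' @export
filter_by_rsq <- function(catalog, threshold = 0.3) {
  if (!identical(catalog_level(catalog), "partial")) {
    stop("filter_by_rsq() applies to level 'partial' catalogs only",
         call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- !is.na(catalog$rsq) & catalog$rsq > threshold
  variant_catalog(catalog[keep, ], level = "partial")
}

#' Derive a common-variant catalog from population frequencies
#'
#' Retains variants with minor allele frequency strictly above
#' `maf_threshold` (default 0.05) and strips genotypes, producing the
#' level-`"none"` catalog used when no sample genotypes are available.
#'
#' @param catalog A [variant_catalog()] with `af` present on every record.
#' @param maf_threshold Strict lower bound on minor allele frequency.
#' @return A level-`"none"` catalog.
#' @export
derive_common_variants <- function(catalog, maf_threshold = 0.05) {
  if (anyNA(catalog$maf)) {
    i <- which(is.na(catalog$maf))[1]
    stop("missing allele frequency at ", catalog$contig[i], ":",
         catalog$pos[i], call. = FALSE)
  }
  out <- catalog[catalog$maf > maf_threshold, ]
  out$zygosity <- "unknown"
  out$rsq <- NA_real_
  variant_catalog(out, level = "none")
}
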