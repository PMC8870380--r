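#' Read / write per-position allele-count tables
#'
#' The allele-count TSV is the substrate of back-tracking and of the
#' background panel: one row per (sample, position, allele pair) with
#' columns `sample_id`, `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#' `alt_count`.
#'
#' @param path file path
#' @return tibble of allele counts
#' @export
read_allele_counts <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(x))) {
    abort(paste0("allele-count table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  x$pos <- as.integer(x$pos)
  x$ref_count <- as.integer(x$ref_count)
  x$alt_count <- as.integer(x$alt_count)
  if (any(x$ref_count < 0 | x$alt_count < 0)) abort("negative allele counts")
  as_tibble(x)
}

#' @rdname read_allele_counts
#' @param counts allele-count tibble
#' @export
write_allele_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort sample metadata
#'
#' TSV with columns `sample_id`, `patient_id`, `stage`, `months_before_mm`,
#' `seq_mode`; validated with [validate_samples()].
#'
#' @param path file path
#' @param require_mm passed to [validate_samples()]
#' @return tibble of samples
#' @export
read_cohort_samples <- function(path, require_mm = TRUE) {
  x <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  x$months_before_mm <- as.integer(x$months_before_mm)
  validate_samples(x, require_mm = require_mm)
  x
}

#' @rdname read_cohort_samples
#' @param samples sample tibble
#' @export
write_cohort_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant calls as a minimal VCF
#'
#' Emits a VCFv4.2 file with `DP` (total depth) and `AD` (ref,alt depths) in
#' the INFO field, one biallelic record per call. Consequence, class and
#' gene annotations travel in a sidecar TSV (see [write_annotations()]), as
#' they come from an external annotation step.
#'
#' @param calls variant-call tibble (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`)
#' @param path output file
#' @export
write_variant_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls) > 0L) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d,%d",
            calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
            as.integer(calls$depth),
            as.integer(calls$depth) - as.integer(calls$alt_count),
            as.integer(calls$alt_count))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal variant VCF
#'
#' Parses CHROM/POS/REF/ALT plus `DP` and `AD` from the INFO column (via the
#' vcfR package) and, when given, joins a sidecar annotation table keyed by
#' chrom:pos:ref:alt. Multi-allelic records are rejected: split them
#' upstream (e.g. `bcftools norm -m-`).
#'
#' @param path VCF file
#' @param annotations optional annotation tibble from [read_annotations()]
#' @return variant-call tibble with `vaf` computed as `alt_count / depth`
#' @export
read_variant_vcf <- function(path, annotations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_variant_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    calls <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), depth = integer(),
                    alt_count = integer(), vaf = numeric())
  } else {
    if (any(grepl(",", fix$ALT, fixed = TRUE))) {
      abort("multi-allelic VCF records found; split them upstream")
    }
    dp <- as.integer(vcfR::extract.info(v, "DP"))
    ad <- vcfR::extract.info(v, "AD")
    alt_count <- as.integer(vapply(strsplit(ad, ",", fixed = TRUE),
                                   function(x) x[2], character(1)))
    calls <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, depth = dp,
                    alt_count = alt_count,
                    vaf = ifelse(dp > 0, alt_count / dp, NA_real_))
  }
  if (!is.null(annotations)) {
    calls <- dplyr::left_join(calls, annotations,
                              by = c("chrom", "pos", "ref", "alt"))
  }
  calls
}

#' Read / write the sidecar variant annotation table
#'
#' TSV keyed by `chrom`, `pos`, `ref`, `alt` with columns `gene`,
#' `consequence` and `classification`, as produced by an external annotation
#' and classification step.
#'
#' @param path file path
#' @return tibble of annotations
#' @export
read_annotations <- function(path) {
  x <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "classification")
  if (!all(need %in% names(x))) {
    abort(paste0("annotation table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  x$pos <- as.integer(x$pos)
  bad <- !x$consequence %in% consequence_levels
  if (any(bad)) {
    abort(paste0("unknown consequence value(s): ",
                 paste(unique(x$consequence[bad]), collapse = ", ")))
  }
  x
}

#' @rdname read_annotations
#' @param annotations annotation tibble
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the same plain-text formats the real-data path reads: per-sample
#' metadata and allele counts as TSV, MM-phase calls as one minimal VCF per
#' patient plus a shared annotation TSV, and the configuration as YAML
#' (when the yaml package is available).
#'
#' @param cohort a [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_samples(cohort$samples, file.path(dir, "samples.tsv"))
  write_allele_counts(cohort$counts, file.path(dir, "counts.tsv"))
  for (pid in unique(cohort$calls$patient_id)) {
    write_variant_vcf(cohort$calls[cohort$calls$patient_id == pid, ],
                      file.path(dir, paste0(pid, "_mm.vcf")))
  }
  ann <- cohort$calls[, c("chrom", "pos", "ref", "alt", "gene",
                          "consequence", "classification")]
  write_annotations(ann, file.path(dir, "annotations.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- unclass(cohort$config)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Parse "chrom:pos:ref:alt" keys back into columns
#' @param keys character vector of variant keys
#' @return tibble with `chrom`, `pos`, `ref`, `alt`
#' @export
parse_variant_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) abort("malformed variant key")
  tibble(chrom = vapply(parts, `[`, "", 1L),
         pos = as.integer(vapply(parts, `[`, "", 2L)),
         ref = vapply(parts, `[`, "", 3L),
         alt = vapply(parts, `[`, "", 4L))
}
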