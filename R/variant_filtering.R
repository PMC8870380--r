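#' Filter configuration for MM-phase variant calls
#'
#' Encodes the call-retention cascade applied to variants detected at the
#' multiple-myeloma timepoint before they are tracked backwards:
#' total depth strictly above `min_coverage_exclusive` reads, VAF at or above
#' `min_vaf`, a protein-altering consequence, a pathogenicity class of
#' pathogenic / likely pathogenic / VUS, and (optionally) membership of the
#' targeted gene panel.
#'
#' @param min_vaf minimum variant allele frequency, inclusive (default 0.01)
#' @param min_coverage_exclusive depth threshold, strict `>` (default 30)
#' @param kept_consequences consequence classes retained
#' @param kept_classifications pathogenicity classes retained
#' @param restrict_to_panel drop calls in genes off the panel (default TRUE)
#' @return an object of class `filter_config`
#' @export
filter_config <- function(min_vaf = 0.01,
                          min_coverage_exclusive = 30L,
                          kept_consequences = c("missense", "stop_gain",
                                                "frameshift", "splice_site"),
                          kept_classifications = c("pathogenic",
                                                   "likely_pathogenic", "VUS"),
                          restrict_to_panel = TRUE) {
  if (!(min_vaf > 0 && min_vaf <= 1)) abort("min_vaf must be in (0, 1]")
  if (min_coverage_exclusive < 0) abort("min_coverage_exclusive must be >= 0")
  structure(list(min_vaf = min_vaf,
                 min_coverage_exclusive = as.integer(min_coverage_exclusive),
                 kept_consequences = kept_consequences,
                 kept_classifications = kept_classifications,
                 restrict_to_panel = isTRUE(restrict_to_panel)),
            class = "filter_config")
}

consequence_levels <- c("missense", "stop_gain", "frameshift", "splice_site",
                        "synonymous", "other")
classification_levels <- c("pathogenic", "likely_pathogenic", "VUS",
                           "benign", "likely_benign", "unclassified")

validate_calls <- function(calls) {
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_count", "vaf",
            "consequence", "classification", "gene")
  if (!all(need %in% names(calls))) {
    abort(paste0("variant calls must have columns: ", paste(need, collapse = ", ")))
  }
  multi <- grepl(",", calls$alt, fixed = TRUE)
  if (any(multi)) {
    abort(paste0("multi-allelic record(s) must be split upstream: ",
                 paste(variant_key(calls$chrom, calls$pos, calls$ref,
                                   calls$alt)[multi], collapse = ", ")))
  }
  bad_allele <- !grepl("^[ACGT]+$", calls$ref) | !grepl("^[ACGT]+$", calls$alt)
  if (any(bad_allele)) {
    abort(paste0("invalid allele characters in record(s): ",
                 paste(variant_key(calls$chrom, calls$pos, calls$ref,
                                   calls$alt)[bad_allele], collapse = ", ")))
  }
  unnorm <- !mapply(is_normalized, calls$ref, calls$alt)
  if (any(unnorm)) {
    abort(paste0("unnormalized record(s) (shared prefix/suffix not trimmed): ",
                 paste(variant_key(calls$chrom, calls$pos, calls$ref,
                                   calls$alt)[unnorm], collapse = ", ")))
  }
  if (any(calls$alt_count > calls$depth)) abort("alt_count exceeds depth")
  invisible(calls)
}

#' Apply the MM-call filter cascade
#'
#' Returns exactly the calls passing every predicate of `config`, in input
#' order; the input is never modified. Records lacking a classification
#' (`NA`) are treated as "unclassified".
#'
#' @param calls tibble of variant calls with columns `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`, `vaf`, `consequence`, `classification`,
#'   `gene`
#' @param panel a [gene_panel()]; used when `config$restrict_to_panel` is TRUE
#' @param config a [filter_config()]
#' @return the retained subset of `calls`
#' @export
filter_calls <- function(calls, panel = load_panel_fixture(),
                         config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) return(calls)
  validate_calls(calls)
  classification <- ifelse(is.na(calls$classification), "unclassified",
                           calls$classification)
  keep <- calls$depth > config$min_coverage_exclusive &
    calls$vaf >= config$min_vaf &
    calls$consequence %in% config$kept_consequences &
    classification %in% config$kept_classifications
  if (config$restrict_to_panel) {
    keep <- keep & panel_contains(panel, calls$gene)
  }
  calls[keep, , drop = FALSE]
}

#' Reasons each call was excluded (audit log)
#'
#' Companion to [filter_calls()]: one row per input record with a logical
#' column per predicate and a semicolon-separated `excluded_because` string
#' (empty for retained records).
#'
#' @inheritParams filter_calls
#' @return tibble with the variant key, per-predicate pass flags, `retained`
#'   and `excluded_because`
#' @export
filter_audit <- function(calls, panel = load_panel_fixture(),
                         config = filter_config()) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) {
    return(tibble(key = character(), pass_coverage = logical(),
                  pass_vaf = logical(), pass_consequence = logical(),
                  pass_classification = logical(), pass_panel = logical(),
                  retained = logical(), excluded_because = character()))
  }
  validate_calls(calls)
  classification <- ifelse(is.na(calls$classification), "unclassified",
                           calls$classification)
  aud <- tibble(
    key = variant_key(calls$chrom, calls$pos, calls$ref, calls$alt),
    pass_coverage = calls$depth > config$min_coverage_exclusive,
    pass_vaf = calls$vaf >= config$min_vaf,
    pass_consequence = calls$consequence %in% config$kept_consequences,
    pass_classification = classification %in% config$kept_classifications,
    pass_panel = if (config$restrict_to_panel) panel_contains(panel, calls$gene)
                 else TRUE
  )
  fails <- cbind(coverage = !aud$pass_coverage, vaf = !aud$pass_vaf,
                 consequence = !aud$pass_consequence,
                 classification = !aud$pass_classification,
                 panel = !aud$pass_panel)
  aud$retained <- rowSums(fails) == 0L
  aud$excluded_because <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  aud
}

is_normalized <- function(ref, alt) {
  if (ref == alt) return(FALSE)
  nr <- nchar(ref); na <- nchar(alt)
  same_last <- substr(ref, nr, nr) == substr(alt, na, na)
  # a shared last base means the record can be trimmed (both alleles > 1 base)
  # or, for an indel, left-shifted through the reference
  if (same_last && (nr > 1L || na > 1L)) return(FALSE)
  # a shared first base is only the VCF anchor convention when an allele is
  # down to a single base
  if (nr > 1L && na > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    return(FALSE)
  }
  TRUE
}

#' Normalize a biallelic variant
#'
#' Left-aligns and parsimony-trims a variant representation: shared suffix
#' bases are removed (extending to the left through the reference context when
#' an allele would become empty, as for indels in repeat runs), then shared
#' prefix bases are removed while both alleles keep at least one base. SNVs
#' are returned unchanged and the operation is idempotent.
#'
#' Left-alignment through repeats requires flanking reference sequence; pass
#' it via `context`/`context_start`. Without context the representation is
#' trimmed only as far as possible without inventing reference bases.
#'
#' @param chrom chromosome name
#' @param pos 1-based position of the first `ref` base
#' @param ref,alt allele strings over A/C/G/T, `ref != alt`, non-empty
#' @param context optional reference sequence string covering the variant site
#'   and its left flank
#' @param context_start 1-based chromosome position of `substr(context, 1, 1)`
#' @return list with elements `chrom`, `pos`, `ref`, `alt`
#' @export
#' @examples
#' normalize_variant("chr1", 100, "A", "G")            # SNV: unchanged
#' ctx <- "GGGTTTTTTA"
#' normalize_variant("chr1", 8, "TT", "T", context = ctx, context_start = 1)
normalize_variant <- function(chrom, pos, ref, alt,
                              context = NULL, context_start = NULL) {
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    abort("alleles must be non-empty strings over A, C, G, T")
  }
  if (ref == alt) abort("ref and alt must differ")
  pos <- as.integer(pos)
  ctx_base <- function(p) {
    if (is.null(context)) return(NA_character_)
    i <- p - as.integer(context_start) + 1L
    if (i < 1L || i > nchar(context)) return(NA_character_)
    substr(context, i, i)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) != substr(alt, na, na) || (nr == 1L && na == 1L)) {
      break
    }
    if (nr == 1L || na == 1L) {
      # stripping the shared last base would empty an allele: left-extend
      b <- ctx_base(pos - 1L)
      if (is.na(b)) break  # no context available; cannot shift further
      ref <- paste0(b, substr(ref, 1L, nr - 1L))
      alt <- paste0(b, substr(alt, 1L, na - 1L))
      pos <- pos - 1L
    } else {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Flag a variant as possible clonal hematopoiesis (CHIP)
#'
#' Somatic variants in hematopoiesis-associated genes whose precursor-stage
#' VAF is already close to the MM-stage VAF are suspicious for clonal
#' hematopoiesis of indeterminate potential rather than the myeloma clone.
#' This is an annotation only; flagged calls are never removed.
#'
#' @param gene gene symbol of the call
#' @param precursor_vaf highest precursor-stage VAF observed, or `NA` when the
#'   variant was not detected in any precursor sample
#' @param mm_vaf VAF at the MM timepoint (> 0)
#' @param chip_genes genes attributable to clonal hematopoiesis
#' @param ratio_threshold flag when `precursor_vaf >= ratio_threshold * mm_vaf`
#'   (in (0, 1])
#' @return logical
#' @export
annotate_chip_flag <- function(gene, precursor_vaf, mm_vaf,
                               chip_genes = c("DNMT3A", "IDH1", "IDH2",
                                              "ASXL1", "TET2"),
                               ratio_threshold = 0.75) {
  if (!(ratio_threshold > 0 && ratio_threshold <= 1)) {
    abort("ratio_threshold must be in (0, 1]")
  }
  stopifnot(mm_vaf > 0)
  if (!gene %in% chip_genes) return(FALSE)
  if (is.na(precursor_vaf)) return(FALSE)
  precursor_vaf >= ratio_threshold * mm_vaf
}
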