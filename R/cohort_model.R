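#' Gene-symbol normalization map for the bundled cohort table
#'
#' The published patient table uses a few gene spellings that differ from the
#' panel's HGNC symbols (`HIST1HE`, `HISTH1D`, `IKBK`). Both forms are kept:
#' the cohort fixture stores the verbatim spelling, and this map translates to
#' panel symbols for membership checks and tallies.
#'
#' @param genes character vector of gene symbols (verbatim spellings allowed)
#' @return character vector of the same length with panel symbols substituted
#'   where a normalization is known; all other symbols pass through unchanged.
#' @export
#' @examples
#' normalize_gene_symbols(c("IKBK", "KRAS", "HIST1HE"))
normalize_gene_symbols <- function(genes) {
  map <- c(HIST1HE = "HIST1H1E", HISTH1D = "HIST1H1D", IKBK = "IKBKB")
  hit <- genes %in% names(map)
  genes[hit] <- unname(map[genes[hit]])
  genes
}

#' Construct a gene panel
#'
#' A gene panel is the set of genes whose coding exons or hotspot positions a
#' targeted assay interrogates. Regions are optional; when present they are
#' 1-based inclusive intervals.
#'
#' @param genes character vector of unique gene symbols (non-empty)
#' @param regions optional data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive)
#' @return an object of class `gene_panel`: a list with elements `genes` and
#'   `regions`.
#' @export
gene_panel <- function(genes, regions = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0L) abort("a gene panel must contain at least one gene")
  if (anyDuplicated(genes)) abort("gene panel symbols must be unique")
  if (any(is.na(genes) | genes == "")) abort("gene panel symbols must be non-missing")
  if (!is.null(regions)) {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(regions)))
    if (any(regions$end < regions$start)) abort("panel regions must have end >= start")
  }
  structure(list(genes = genes, regions = regions), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", length(x$genes), " genes: ",
      paste(head(x$genes, 5), collapse = ", "),
      if (length(x$genes) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Test panel membership
#'
#' Membership is evaluated after gene-symbol normalization, so the verbatim
#' cohort-table spellings (e.g. `IKBK`) match their panel symbols.
#'
#' @param panel a [gene_panel()]
#' @param genes character vector of gene symbols
#' @return logical vector, `TRUE` where the (normalized) symbol is on the panel
#' @export
panel_contains <- function(panel, genes) {
  stopifnot(inherits(panel, "gene_panel"))
  normalize_gene_symbols(genes) %in% panel$genes
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mmbacktrack")
  if (p == "") {
    # during development (pkgload) inst/ may be on the source path
    p <- system.file("inst", "extdata", file, package = "mmbacktrack")
  }
  if (p == "") abort(paste0("bundled fixture not found: ", file))
  p
}

#' Load the bundled 81-gene myeloma panel
#'
#' The panel covers coding exons or hotspot positions of 81 genes recurrently
#' mutated in multiple myeloma and its precursor conditions.
#'
#' @return a [gene_panel()] with 81 genes and no region annotation
#' @export
#' @examples
#' panel <- load_panel_fixture()
#' panel_contains(panel, c("KRAS", "NRAS", "TP53"))
load_panel_fixture <- function() {
  genes <- readLines(fixture_path("panel_genes.txt"))
  genes <- genes[genes != ""]
  if (length(genes) != 81L) {
    abort("panel fixture corrupt: expected 81 gene symbols")
  }
  gene_panel(genes)
}

#' Load the bundled serial-sample cohort table
#'
#' Returns the characteristics of the 21 patients who progressed from a
#' low/intermediate-risk myeloma precursor condition (MGUS or SMM) to multiple
#' myeloma, together with the genes in which somatic variants were detected in
#' their MM-phase bone-marrow sample.
#'
#' @return a list with two tibbles:
#' \describe{
#'   \item{patients}{one row per patient: `patient_id`, `precursor_stage`
#'     (stage at the first available sample), `gender`, `age_precursor_dx`,
#'     `age_mm_dx`, `ttp_months` (time to progression), `n_serial_samples`,
#'     `precursor_detected` (any variant found in a precursor sample),
#'     `mm_detected`, `first_precursor_negative` (variant absent from the
#'     earliest precursor sample(s) but found later), `passed_through_smm`.}
#'   \item{variants}{one row per detected MM variant: `patient_id`,
#'     `gene_raw` (verbatim spelling), `gene` (normalized panel symbol).}
#' }
#' @param path optional path to a cohort table in the bundled TSV layout;
#'   defaults to the shipped fixture
#' @export
#' @examples
#' cohort <- load_table1_fixture()
#' nrow(cohort$patients)   # 21
#' nrow(cohort$variants)   # 29
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) path <- fixture_path("table1.tsv")
  raw <- read.delim(path, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patient_id", "precursor_stage", "gender", "age_precursor_dx",
            "age_mm_dx", "ttp_months", "n_serial_samples",
            "precursor_detected", "mm_detected", "first_precursor_negative",
            "passed_through_smm", "genes")
  if (!all(need %in% names(raw))) abort("cohort fixture corrupt: missing columns")

  patients <- tibble(
    patient_id = raw$patient_id,
    precursor_stage = raw$precursor_stage,
    gender = raw$gender,
    age_precursor_dx = as.integer(raw$age_precursor_dx),
    age_mm_dx = as.integer(raw$age_mm_dx),
    ttp_months = as.integer(raw$ttp_months),
    n_serial_samples = as.integer(raw$n_serial_samples),
    precursor_detected = raw$precursor_detected == "X",
    mm_detected = raw$mm_detected == "X",
    first_precursor_negative = as.logical(raw$first_precursor_negative),
    passed_through_smm = as.logical(raw$passed_through_smm)
  )
  validate_patients(patients)

  gene_lists <- strsplit(ifelse(is.na(raw$genes), "", raw$genes), ",", fixed = TRUE)
  variants <- tibble(
    patient_id = rep(patients$patient_id, lengths(gene_lists)),
    gene_raw = trimws(unlist(gene_lists))
  )
  variants$gene <- normalize_gene_symbols(variants$gene_raw)

  # internal consistency: "nd"/"X" flags must agree with the gene lists
  has_var <- patients$patient_id %in% variants$patient_id
  if (!identical(has_var, patients$mm_detected)) {
    abort("cohort fixture corrupt: detection flags disagree with gene lists")
  }
  list(patients = patients, variants = variants)
}

validate_patients <- function(patients) {
  stopifnot(is.data.frame(patients))
  if (anyDuplicated(patients$patient_id)) abort("duplicate patient_id")
  if (!all(patients$gender %in% c("F", "M"))) abort("gender must be F or M")
  if (!all(patients$precursor_stage %in% c("MGUS", "SMM"))) {
    abort("precursor_stage must be MGUS or SMM")
  }
  if (any(patients$age_mm_dx < patients$age_precursor_dx)) {
    abort("age at MM diagnosis must be >= age at precursor diagnosis")
  }
  if (any(patients$ttp_months <= 0)) abort("time to progression must be positive")
  invisible(patients)
}

#' Validate a sample table
#'
#' A cohort sample table has one row per sequenced bone-marrow sample:
#' `sample_id`, `patient_id`, `stage` (MGUS/SMM/MM), `months_before_mm`
#' (0 for the MM sample, > 0 for precursor samples) and `seq_mode`
#' (standard/deep). Each patient must have exactly one MM sample.
#'
#' @param samples data frame of samples
#' @param require_mm require one MM sample at 0 months per patient
#'   (background-only samples from unrelated donors are exempt)
#' @return the validated table, invisibly
#' @export
validate_samples <- function(samples, require_mm = TRUE) {
  need <- c("sample_id", "patient_id", "stage", "months_before_mm", "seq_mode")
  if (!all(need %in% names(samples))) {
    abort(paste0("sample table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (!all(samples$stage %in% c("MGUS", "SMM", "MM", "background"))) {
    abort("stage must be one of MGUS, SMM, MM, background")
  }
  if (!all(samples$seq_mode %in% c("standard", "deep"))) {
    abort("seq_mode must be standard or deep")
  }
  if (any(samples$months_before_mm < 0)) abort("months_before_mm must be >= 0")
  bad_mm <- samples$stage == "MM" & samples$months_before_mm != 0
  if (any(bad_mm)) abort("MM samples must have months_before_mm = 0")
  bad_pre <- samples$stage %in% c("MGUS", "SMM") & samples$months_before_mm <= 0
  if (any(bad_pre)) abort("precursor samples must have months_before_mm > 0")
  if (require_mm) {
    cohort <- samples[samples$stage != "background", ]
    n_mm <- tapply(cohort$stage == "MM", cohort$patient_id, sum)
    if (any(n_mm != 1L)) abort("each patient must have exactly one MM sample")
  }
  invisible(samples)
}

#' Allele-frequency of an allele-count record
#'
#' Defined as `alt_count / (ref_count + alt_count)`; `NaN` when both counts
#' are zero (no coverage).
#'
#' @param ref_count,alt_count non-negative integer vectors
#' @return numeric vector of frequencies
#' @export
allele_frequency <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0)) abort("allele counts must be non-negative")
  alt_count / (ref_count + alt_count)
}

#' Build the canonical variant key "chrom:pos:ref:alt"
#' @param chrom,pos,ref,alt vectors describing biallelic variants
#' @return character vector of keys
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
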