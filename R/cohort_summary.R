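#' Tally detected variants per gene
#'
#' Counts every listed variant once (a gene mutated in two patients counts
#' twice), after normalizing gene spellings to panel symbols. Symbols that
#' remain unknown after normalization are counted under their raw spelling
#' with a warning.
#'
#' @param variants tibble with a `gene` (or `gene_raw`) column, one row per
#'   detected variant
#' @param panel a [gene_panel()] used to recognize symbols
#' @return named integer vector, gene -> variant count, sorted by
#'   decreasing count then symbol
#' @export
#' @examples
#' gene_tally(load_table1_fixture()$variants)
gene_tally <- function(variants, panel = load_panel_fixture()) {
  if (nrow(variants) == 0L) return(integer(0))
  genes <- if ("gene" %in% names(variants)) variants$gene else variants$gene_raw
  genes <- normalize_gene_symbols(genes)
  unknown <- setdiff(unique(genes), panel$genes)
  if (length(unknown) > 0L) {
    warn(paste0("gene symbol(s) not on the panel, counted under raw symbol: ",
                paste(unknown, collapse = ", ")))
  }
  tab <- table(genes)
  out <- setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Cohort-level summary statistics
#'
#' Computes the patient-characteristics and mutation-burden statistics of a
#' serial-sample cohort: counts, sex split, stage at first sample, ages,
#' time to progression, variant and gene totals, and the split of patients
#' by where their variants were detectable.
#'
#' Medians over even-sized sets are the midpoint of the two central order
#' statistics. Displayed percentages are rounded to the nearest integer and
#' the mean variant burden to one decimal; full-precision values are kept in
#' `*_raw` fields.
#'
#' @param patients patient table as in [load_table1_fixture()] (columns
#'   `patient_id`, `gender`, `precursor_stage`, `passed_through_smm`,
#'   `age_precursor_dx`, `age_mm_dx`, `ttp_months`, `n_serial_samples`)
#' @param variants variant table with `patient_id` and `gene` columns (one
#'   row per detected MM variant)
#' @param classifications optional tibble from [classify_patients()]; when
#'   omitted it is derived from fixture-style `precursor_detected` /
#'   `mm_detected` flags on `patients`
#' @param panel a [gene_panel()]
#' @return object of class `cohort_summary` (a list of named statistics,
#'   including `gene_tally`)
#' @export
#' @examples
#' fx <- load_table1_fixture()
#' summarize_cohort(fx$patients, fx$variants)
summarize_cohort <- function(patients, variants, classifications = NULL,
                             panel = load_panel_fixture()) {
  if (nrow(patients) == 0L) abort("cannot summarize an empty cohort")
  if (!all(variants$patient_id %in% patients$patient_id)) {
    abort("variant table references unknown patients")
  }
  if (is.null(classifications)) {
    if (!all(c("precursor_detected", "mm_detected") %in% names(patients))) {
      abort(paste0("classifications not given and patient table lacks ",
                   "precursor_detected/mm_detected flags"))
    }
    classifications <- tibble(
      patient_id = patients$patient_id,
      category = ifelse(!patients$mm_detected, "no_variants",
                        ifelse(patients$precursor_detected,
                               "precursor_shared", "mm_only")))
  }
  n <- nrow(patients)
  n_samples <- sum(patients$n_serial_samples)
  tally <- gene_tally(variants, panel)
  n_var <- nrow(variants)
  cat_n <- function(x) sum(classifications$category == x)

  out <- list(
    n_patients = n,
    n_samples_total = n_samples,
    mean_samples_per_patient = n_samples / n,
    pct_female = round(100 * mean(patients$gender == "F")),
    pct_male = round(100 * mean(patients$gender == "M")),
    frac_female_raw = mean(patients$gender == "F"),
    n_mgus_first = sum(patients$precursor_stage == "MGUS"),
    n_smm_first = sum(patients$precursor_stage == "SMM"),
    n_passed_through_smm = sum(patients$passed_through_smm),
    n_multi_sample_patients = sum(patients$n_serial_samples > 2),
    median_age_precursor = median(patients$age_precursor_dx),
    median_age_mm = median(patients$age_mm_dx),
    median_ttp_months = median(patients$ttp_months),
    ttp_range_months = range(patients$ttp_months),
    n_variants_total = n_var,
    n_genes_mutated = length(tally),
    mean_variants_per_patient = round(n_var / n, 1),
    mean_variants_per_patient_raw = n_var / n,
    n_patients_no_variants = cat_n("no_variants"),
    n_patients_with_variants = n - cat_n("no_variants"),
    n_patients_mm_only = cat_n("mm_only"),
    n_patients_precursor_shared = cat_n("precursor_shared"),
    gene_tally = tally
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  %d patients, %d samples (mean %.2f/patient)\n",
              x$n_patients, x$n_samples_total, x$mean_samples_per_patient))
  cat(sprintf("  %.0f%% female / %.0f%% male; %d MGUS-first, %d SMM-first, %d passed through SMM\n",
              x$pct_female, x$pct_male, x$n_mgus_first, x$n_smm_first,
              x$n_passed_through_smm))
  cat(sprintf("  median age %s (precursor) / %s (MM); median TTP %s months (range %s-%s)\n",
              format(x$median_age_precursor), format(x$median_age_mm),
              format(x$median_ttp_months),
              format(x$ttp_range_months[1]), format(x$ttp_range_months[2])))
  cat(sprintf("  %d variants in %d genes (mean %.1f/patient)\n",
              x$n_variants_total, x$n_genes_mutated,
              x$mean_variants_per_patient))
  cat(sprintf("  patients: %d without variants, %d MM-only, %d precursor-shared\n",
              x$n_patients_no_variants, x$n_patients_mm_only,
              x$n_patients_precursor_shared))
  invisible(x)
}

#' @export
format.cohort_summary <- function(x, ...) {
  utils::capture.output(print(x))
}
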