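#' Assemble per-variant trajectories across a patient's timepoints
#'
#' One trajectory per tracked MM variant: the MM timepoint (0 months before
#' diagnosis, always detected for a tracked variant, VAF from the call) plus
#' one record per precursor sample taken from the detection results. When a
#' (sample, variant) pair was re-tested at deep coverage, the deep result
#' supersedes the standard one — even when still negative.
#'
#' @param calls filtered MM-phase calls with `patient_id` (one row per
#'   tracked variant)
#' @param detections_standard standard-mode detection results from
#'   [backtrack_variants()]
#' @param detections_deep optional deep-mode detection results for re-tested
#'   pairs
#' @param samples sample table (for timepoint months)
#' @return tibble with one row per (variant, timepoint): `patient_id`,
#'   `variant`, `gene`, `sample_id`, `months_before_mm`, `detected`, `vaf`,
#'   `mode`
#' @export
build_trajectories <- function(calls, detections_standard,
                               detections_deep = NULL, samples) {
  if (nrow(calls) == 0L) {
    return(tibble(patient_id = character(), variant = character(),
                  gene = character(), sample_id = character(),
                  months_before_mm = integer(), detected = logical(),
                  vaf = numeric(), mode = character()))
  }
  det <- as_tibble(detections_standard)
  if (!is.null(detections_deep) && nrow(detections_deep) > 0L) {
    deep <- as_tibble(detections_deep)
    deep_key <- paste(deep$sample_id, deep$variant)
    det <- det[!paste(det$sample_id, det$variant) %in% deep_key, ]
    det <- dplyr::bind_rows(det, deep)
  }
  months <- setNames(samples$months_before_mm, samples$sample_id)

  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    pre <- samples[samples$patient_id == v$patient_id &
                     samples$months_before_mm > 0, ]
    d <- det[det$variant == key & det$sample_id %in% pre$sample_id, ]
    missing <- setdiff(pre$sample_id, d$sample_id)
    if (length(missing) > 0L) {
      abort(paste0("missing detection result for variant ", key,
                   " in sample(s): ", paste(missing, collapse = ", ")))
    }
    mm_id <- samples$sample_id[samples$patient_id == v$patient_id &
                                 samples$months_before_mm == 0 &
                                 samples$stage == "MM"]
    rows[[i]] <- tibble(
      patient_id = v$patient_id, variant = key, gene = v$gene,
      sample_id = c(d$sample_id, mm_id),
      months_before_mm = c(as.integer(months[d$sample_id]), 0L),
      detected = c(d$significant, TRUE),
      vaf = c(d$candidate_freq, v$vaf),
      mode = c(d$mode, "standard")
    )
  }
  traj <- dplyr::bind_rows(rows)
  traj[order(traj$patient_id, traj$variant, -traj$months_before_mm), ]
}

#' Per-variant trajectory summary
#'
#' Collapses a trajectory table to one row per variant with its earliest
#' detection time (the largest months-before-MM among detected timepoints;
#' 0 when the variant is only found at the MM timepoint) and whether it was
#' detected in any precursor sample.
#'
#' @param trajectories output of [build_trajectories()]
#' @return tibble: `patient_id`, `variant`, `gene`,
#'   `first_detection_months_before_mm`, `detected_in_precursor`
#' @export
trajectory_summary <- function(trajectories) {
  if (nrow(trajectories) == 0L) {
    return(tibble(patient_id = character(), variant = character(),
                  gene = character(),
                  first_detection_months_before_mm = integer(),
                  detected_in_precursor = logical()))
  }
  trajectories |>
    dplyr::group_by(.data$patient_id, .data$variant, .data$gene) |>
    dplyr::summarise(
      first_detection_months_before_mm =
        max(.data$months_before_mm[.data$detected]),
      detected_in_precursor =
        any(.data$detected & .data$months_before_mm > 0),
      .groups = "drop")
}

#' Classify patients by where their variants were detectable
#'
#' Each patient falls in exactly one category: `no_variants` (nothing passed
#' the MM-phase filter), `mm_only` (variants tracked but none significantly
#' present in any precursor sample), or `precursor_shared` (at least one MM
#' variant already present in a precursor sample).
#'
#' @param traj_summary output of [trajectory_summary()]
#' @param patient_ids all patients in the cohort (so variant-free patients
#'   are classified too)
#' @return tibble: `patient_id`, `category`, `n_variants`
#' @export
classify_patients <- function(traj_summary, patient_ids) {
  per <- traj_summary |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_variants = dplyr::n(),
                     any_precursor = any(.data$detected_in_precursor),
                     .groups = "drop")
  out <- tibble(patient_id = as.character(patient_ids)) |>
    dplyr::left_join(per, by = "patient_id")
  out$n_variants[is.na(out$n_variants)] <- 0L
  out$category <- ifelse(out$n_variants == 0L, "no_variants",
                         ifelse(out$any_precursor, "precursor_shared",
                                "mm_only"))
  out[, c("patient_id", "category", "n_variants")]
}

#' Median and range of first-detection times
#'
#' Summarizes, over precursor-detected variants (one value per variant, not
#' per patient), how many months before MM diagnosis each variant first
#' became significantly detectable.
#'
#' @param traj_summary output of [trajectory_summary()]
#' @return list with `n`, `median`, `range` (months before MM); all `NA`
#'   with `n = 0` when no variant was detected in a precursor sample
#' @export
first_detection_stats <- function(traj_summary) {
  x <- traj_summary$first_detection_months_before_mm[
    traj_summary$detected_in_precursor]
  if (length(x) == 0L) {
    return(list(n = 0L, median = NA_real_, range = c(NA_real_, NA_real_)))
  }
  list(n = length(x), median = median(x), range = range(x))
}

#' Swimmer-style trajectory plot
#'
#' Draws the cohort's detection matrix: one row per variant, months before
#' MM diagnosis on the x axis (reversed), filled points where the variant
#' was significantly detected (sized by VAF) and open points where it was
#' not.
#'
#' @param trajectories output of [build_trajectories()]
#' @return a ggplot object
#' @export
plot_trajectories <- function(trajectories) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_trajectories requires the ggplot2 package")
  }
  tr <- trajectories
  tr$label <- paste0(tr$patient_id, " ", tr$gene)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$months_before_mm,
                                   y = .data$label)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$variant),
                       colour = "grey70") +
    ggplot2::geom_point(data = tr[!tr$detected, ], shape = 1, size = 2) +
    ggplot2::geom_point(data = tr[tr$detected, ],
                        ggplot2::aes(size = .data$vaf), shape = 16) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "months before MM diagnosis", y = NULL,
                  size = "VAF") +
    ggplot2::theme_minimal()
}
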