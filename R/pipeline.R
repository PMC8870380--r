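#' Re-test planned (sample, variant) pairs against deep-coverage counts
#'
#' For every pair in a [plan_deep_retests()] plan, rebuilds the variant's
#' background null from the standard-depth counts (only the candidate
#' samples were resequenced, not the background panel; the per-variant seed
#' reproduces the same panel as the standard-mode test) and tests the
#' deep-coverage candidate counts.
#'
#' @param plan tibble from [plan_deep_retests()]
#' @param deep_counts allele-count table holding deep-mode counts for the
#'   planned pairs
#' @param counts standard-depth allele-count table (background panel source)
#' @param samples sample table
#' @param n_background,min_alt_reads,seed as in [backtrack_variants()]
#' @return deep-mode detection-result tibble with `patient_id`
#' @export
apply_deep_retests <- function(plan, deep_counts, counts, samples,
                               n_background = 10L, min_alt_reads = 3L,
                               seed = 1L) {
  if (nrow(plan) == 0L) {
    return(tibble(sample_id = character(), variant = character(),
                  candidate_freq = numeric(), candidate_alt_count = integer(),
                  candidate_depth = integer(), null_mean = numeric(),
                  null_sd = numeric(), threshold = numeric(),
                  significant = logical(), mode = character(),
                  reason = character(), patient_id = character()))
  }
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    v <- parse_variant_key(plan$variant[i])
    null <- build_background_null(v, counts, samples,
                                  exclude_patient = plan$patient_id[i],
                                  n = n_background, seed = seed)
    cnt <- deep_counts[deep_counts$sample_id == plan$sample_id[i] &
                         deep_counts$chrom == v$chrom &
                         deep_counts$pos == v$pos &
                         deep_counts$ref == v$ref &
                         deep_counts$alt == v$alt, ]
    if (nrow(cnt) == 0L) {
      abort(paste0("no deep counts for ", plan$variant[i], " in sample ",
                   plan$sample_id[i]))
    }
    r <- test_presence(cnt[1, ], null, min_alt_reads, mode = "deep")
    r$patient_id <- plan$patient_id[i]
    rows[[i]] <- r
  }
  dplyr::bind_rows(rows)
}

#' Run the full back-tracking pipeline on a simulated cohort
#'
#' Chains every stage: filter the MM-phase calls, back-track each tracked
#' variant through its patient's precursor samples in standard mode, plan
#' and simulate deep resequencing for the (sample, variant) pairs that were
#' not significant, re-test them, assemble trajectories, classify patients
#' and summarize the cohort.
#'
#' @param cohort a [simulate_cohort()] result
#' @param filter_cfg a [filter_config()]
#' @param n_background background-panel size (default 10)
#' @param min_alt_reads read-support guard (default 3)
#' @param seed seed for background-panel draws and deep resequencing
#' @return list with `calls` (filtered), `detections_standard`, `deep_plan`,
#'   `detections_deep`, `trajectories`, `trajectory_summary`,
#'   `classifications`, `first_detection`, `summary_counts`
#' @export
run_pipeline <- function(cohort, filter_cfg = filter_config(),
                         n_background = 10L, min_alt_reads = 3L,
                         seed = cohort$config$seed) {
  panel <- load_panel_fixture()
  filtered <- filter_calls(cohort$calls, panel, filter_cfg)

  det_std <- backtrack_variants(filtered, cohort$counts, cohort$samples,
                                n_background = n_background,
                                min_alt_reads = min_alt_reads, seed = seed)
  plan <- plan_deep_retests(det_std)

  deep_counts <- dplyr::bind_rows(lapply(
    unique(plan$sample_id), function(sid) {
      resequence_deep(sid, plan$variant[plan$sample_id == sid], cohort,
                      seed = seed + 1L)
    }))
  det_deep <- apply_deep_retests(plan, deep_counts, cohort$counts,
                                 cohort$samples, n_background = n_background,
                                 min_alt_reads = min_alt_reads, seed = seed)

  traj <- build_trajectories(filtered, det_std, det_deep, cohort$samples)
  ts <- trajectory_summary(traj)
  pids <- unique(cohort$samples$patient_id[cohort$samples$stage != "background"])
  cls <- classify_patients(ts, pids)

  list(calls = filtered,
       detections_standard = det_std,
       deep_plan = plan,
       detections_deep = det_deep,
       trajectories = traj,
       trajectory_summary = ts,
       classifications = cls,
       first_detection = first_detection_stats(ts),
       summary_counts = table(cls$category))
}
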