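test_that("identical seeds reproduce the cohort exactly; seeds matter", {
  a <- simulate_cohort(sim_config(n_patients = 4, seed = 7))
  b <- simulate_cohort(sim_config(n_patients = 4, seed = 7))
  expect_identical(a$samples, b$samples)
  expect_identical(a$counts, b$counts)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(n_patients = 4, seed = 8))
  expect_false(identical(a$counts, c2$counts))
})

test_that("cohort structure matches the study design", {
  cohort <- simulate_cohort(sim_config(n_patients = 10, seed = 3))
  cs <- cohort$samples[cohort$samples$stage != "background", ]
  # one MM sample per patient at 0 months, precursors strictly earlier
  per <- split(cs, cs$patient_id)
  expect_equal(length(per), 10L)
  for (s in per) {
    expect_equal(sum(s$stage == "MM"), 1L)
    expect_equal(s$months_before_mm[s$stage == "MM"], 0L)
    expect_true(all(s$months_before_mm[s$stage != "MM"] > 0))
    expect_gte(nrow(s), 2L); expect_lte(nrow(s), 7L)
  }
  # counts exist for every sample at every variant position
  expect_equal(nrow(cohort$counts),
               nrow(cohort$samples) * nrow(cohort$truth$variants))
})

test_that("a zero-variant configuration emits no calls", {
  cohort <- simulate_cohort(sim_config(n_patients = 5,
                                       mean_variants_per_patient = 0,
                                       seed = 5))
  expect_equal(nrow(cohort$calls), 0L)
  expect_equal(nrow(cohort$truth$variants), 0L)
  expect_equal(nrow(cohort$counts), 0L)
})

test_that("error-free MM counts stay inside exact binomial bounds", {
  # true MM VAF pinned at 0.10, no sequencing error, depth ~1000
  cfg <- sim_config(n_patients = 12, vaf_mm_min = 0.1, vaf_mm_max = 0.1,
                    fraction_precursor_absent = 0, error_rate_mean = 0,
                    depth_standard = 1000, depth_deep = 4000,
                    depth_dispersion = 1e9, seed = 11)
  cohort <- simulate_cohort(cfg)
  mm_ids <- cohort$samples$sample_id[cohort$samples$stage == "MM"]
  tv <- cohort$truth$true_vaf
  own_mm <- tv[tv$sample_id %in% mm_ids & tv$true_vaf > 0, ]
  cnt <- dplyr::inner_join(cohort$counts, own_mm, by = "sample_id",
                           relationship = "many-to-many") |>
    dplyr::filter(variant_key(chrom, pos, ref, alt) == key)
  expect_gt(nrow(cnt), 5L)
  dp <- cnt$ref_count + cnt$alt_count
  # central 99.9% binomial interval at the realized depth
  lo <- qbinom(5e-4, dp, 0.10); hi <- qbinom(1 - 5e-4, dp, 0.10)
  expect_true(all(cnt$alt_count >= lo & cnt$alt_count <= hi))
})

test_that("true VAFs are zero before clone origin and grow toward MM", {
  for (model in c("stepwise", "logistic")) {
    cohort <- simulate_cohort(sim_config(n_patients = 15,
                                         growth_model = model, seed = 21))
    tv <- dplyr::inner_join(
      cohort$truth$true_vaf,
      cohort$samples[, c("sample_id", "patient_id", "months_before_mm")],
      by = "sample_id")
    vars <- cohort$truth$variants
    for (i in seq_len(nrow(vars))) {
      own <- tv[tv$key == vars$key[i] & tv$patient_id == vars$patient_id[i], ]
      own <- own[order(-own$months_before_mm), ]
      expect_true(all(own$true_vaf[own$months_before_mm >
                                     vars$origin_months[i]] == 0))
      present <- own$true_vaf[own$months_before_mm <= vars$origin_months[i]]
      # non-decreasing toward MM, ending at the MM VAF
      expect_true(all(diff(present) >= -1e-12))
      expect_equal(own$true_vaf[own$months_before_mm == 0], vars$vaf_mm[i])
      # other patients carry nothing
      other <- tv[tv$key == vars$key[i] & tv$patient_id != vars$patient_id[i], ]
      expect_true(all(other$true_vaf == 0))
    }
  }
})

test_that("deep resequencing scales expected alt reads with depth", {
  # one patient, one variant pinned at VAF 0.004 with no error
  cfg <- sim_config(n_patients = 2, mean_variants_per_patient = 3,
                    vaf_mm_min = 0.004, vaf_mm_max = 0.004,
                    fraction_precursor_absent = 0, error_rate_mean = 0,
                    depth_standard = 600, depth_deep = 3400, seed = 13)
  cohort <- simulate_cohort(cfg)
  vars <- cohort$truth$variants
  expect_gt(nrow(vars), 0L)
  v <- vars[1, ]
  mm_id <- cohort$samples$sample_id[cohort$samples$patient_id == v$patient_id &
                                      cohort$samples$stage == "MM"]
  deep <- dplyr::bind_rows(lapply(1:400, function(i)
    resequence_deep(mm_id, v$key, cohort, seed = 1000L + i)))
  # E[alt] = depth * VAF: ~13.6 deep vs ~2.4 at standard depth
  expect_equal(mean(deep$alt_count), 3400 * 0.004, tolerance = 0.15)
  std <- cohort$counts[cohort$counts$sample_id == mm_id &
                         cohort$counts$pos == v$pos, ]
  expect_lt(std$alt_count, 15)  # standard depth cannot yield deep-scale support

  # empty request, unknown sample / position
  expect_equal(nrow(resequence_deep(mm_id, character(0), cohort)), 0L)
  expect_error(resequence_deep("nope", v$key, cohort), "unknown sample")
  expect_error(resequence_deep(mm_id, "chrX:1:A:T", cohort),
               "unknown position")
})

test_that("error-only positions resequence to the configured error rate", {
  cfg <- sim_config(n_patients = 2, mean_variants_per_patient = 2,
                    fraction_precursor_absent = 1, error_rate_mean = 2e-3,
                    depth_deep = 5000, seed = 17)
  cohort <- simulate_cohort(cfg)
  vars <- cohort$truth$variants
  expect_true(all(vars$precursor_absent))
  v <- vars[1, ]
  pre_id <- cohort$samples$sample_id[cohort$samples$patient_id == v$patient_id &
                                       cohort$samples$months_before_mm > 0][1]
  deep <- dplyr::bind_rows(lapply(1:300, function(i)
    resequence_deep(pre_id, v$key, cohort, seed = 2000L + i)))
  freq <- deep$alt_count / (deep$ref_count + deep$alt_count)
  # law of large numbers: mean frequency approaches this position's error rate
  se <- sqrt(v$error_rate / (5000 * 300))
  expect_lt(abs(mean(freq) - v$error_rate), 5 * se + 1e-5)
})

test_that("pooled frequency recovers truth at extreme depth", {
  cfg <- sim_config(n_patients = 3, depth_standard = 1e5, depth_deep = 2e5,
                    fraction_precursor_absent = 0, seed = 29)
  cohort <- simulate_cohort(cfg)
  vars <- cohort$truth$variants
  tv <- cohort$truth$true_vaf
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    cnt <- cohort$counts[cohort$counts$pos == v$pos &
                           cohort$counts$chrom == v$chrom, ]
    cnt <- dplyr::inner_join(cnt, tv[tv$key == v$key, ], by = "sample_id")
    p_true <- cnt$true_vaf + v$error_rate * (1 - cnt$true_vaf)
    dp <- cnt$ref_count + cnt$alt_count
    pooled_obs <- sum(cnt$alt_count) / sum(dp)
    pooled_exp <- sum(p_true * dp) / sum(dp)
    sd3 <- 3 * sqrt(pooled_exp * (1 - pooled_exp) / sum(dp))
    expect_lt(abs(pooled_obs - pooled_exp), sd3 + 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(depth_deep = 100, depth_standard = 600), "exceed")
  expect_error(sim_config(fraction_precursor_absent = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(timepoints_min = 1), "at least 2")
  expect_error(sim_config(vaf_mm_min = 0.3, vaf_mm_max = 0.1), "vaf_mm_max")
  expect_error(sim_config(depth_dispersion = 0), "positive")
})
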