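#' Configuration for the serial-sample cohort simulator
#'
#' Defines the statistical structure of a simulated targeted-sequencing
#' study: a cohort of patients each with one multiple-myeloma (MM) sample and
#' one or more earlier precursor samples, a small number of somatic variants
#' per patient whose clonal VAF grows toward the MM timepoint, binomial read
#' sampling at two depth regimes, per-position sequencing error, and
#' unrelated background samples carrying error-only reads.
#'
#' Defaults mirror the study design the pipeline targets: 21 patients with
#' 2-7 serial samples each, a mean of 1.4 tracked variants per patient,
#' mean coverage 636x in standard mode and 3410x for deep resequencing, and
#' precursor sampling times spread over 6-166 months before MM diagnosis.
#'
#' @param n_patients number of patients (default 21)
#' @param timepoints_min,timepoints_max samples per patient, drawn uniformly
#'   (default 2-7, including the MM sample)
#' @param mean_variants_per_patient Poisson mean of tracked variants per
#'   patient (default 1.4)
#' @param vaf_mm_min,vaf_mm_max MM-timepoint clone VAF, drawn uniformly
#'   (default 0.02-0.40)
#' @param growth_model `"stepwise"` (absent, then linear growth to the MM
#'   VAF) or `"logistic"` (logit-linear interpolation)
#' @param origin_vaf_frac_min at the first timepoint where a clone is
#'   present, its VAF is this fraction (to 1, drawn uniformly) of the MM VAF
#' @param fraction_precursor_absent probability a variant is truly absent
#'   from every precursor sample (default 0.1)
#' @param depth_standard,depth_deep mean per-position depths of the two
#'   sequencing modes (defaults 636 and 3410 reads; deep must exceed standard)
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution (default 3.5; smaller = more overdispersed)
#' @param error_rate_mean,error_rate_shape per-position error rates are drawn
#'   once per position from Beta(`shape`, `shape * (1 - mean) / mean`)
#'   (default mean 1e-3)
#' @param months_min,months_max range of precursor sampling times in months
#'   before MM diagnosis (default 6-166)
#' @param n_background_samples unrelated error-only samples (default 10)
#' @param seed integer seed governing every draw of the simulation
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients = 21L,
                       timepoints_min = 2L, timepoints_max = 7L,
                       mean_variants_per_patient = 1.4,
                       vaf_mm_min = 0.02, vaf_mm_max = 0.40,
                       growth_model = c("stepwise", "logistic"),
                       origin_vaf_frac_min = 0.2,
                       fraction_precursor_absent = 0.1,
                       depth_standard = 636, depth_deep = 3410,
                       depth_dispersion = 3.5,
                       error_rate_mean = 1e-3, error_rate_shape = 2,
                       months_min = 6L, months_max = 166L,
                       n_background_samples = 10L,
                       seed = 1L) {
  growth_model <- match.arg(growth_model)
  if (depth_deep <= depth_standard) abort("depth_deep must exceed depth_standard")
  probs <- c(fraction_precursor_absent, vaf_mm_min, vaf_mm_max,
             error_rate_mean, origin_vaf_frac_min)
  if (any(probs < 0 | probs > 1)) abort("probabilities/fractions must lie in [0, 1]")
  if (vaf_mm_max < vaf_mm_min) abort("vaf_mm_max must be >= vaf_mm_min")
  if (timepoints_min < 2L) abort("each patient needs at least 2 timepoints")
  if (timepoints_max < timepoints_min) abort("timepoints_max < timepoints_min")
  if (mean_variants_per_patient < 0) abort("mean_variants_per_patient must be >= 0")
  if (depth_dispersion <= 0) abort("depth_dispersion must be positive")
  if (error_rate_shape <= 0) abort("error_rate_shape must be positive")
  if (months_max <= months_min) abort("months_max must exceed months_min")
  if (n_background_samples < 0) abort("n_background_samples must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients),
    timepoints_min = as.integer(timepoints_min),
    timepoints_max = as.integer(timepoints_max),
    mean_variants_per_patient = mean_variants_per_patient,
    vaf_mm_min = vaf_mm_min, vaf_mm_max = vaf_mm_max,
    growth_model = growth_model,
    origin_vaf_frac_min = origin_vaf_frac_min,
    fraction_precursor_absent = fraction_precursor_absent,
    depth_standard = depth_standard, depth_deep = depth_deep,
    depth_dispersion = depth_dispersion,
    error_rate_mean = error_rate_mean, error_rate_shape = error_rate_shape,
    months_min = as.integer(months_min), months_max = as.integer(months_max),
    n_background_samples = as.integer(n_background_samples),
    seed = as.integer(seed)), class = "sim_config")
}

# depth draw: overdispersed counts, truncated at >= 1
draw_depth <- function(n, mu, size) {
  pmax(1L, rnbinom(n, size = size, mu = mu))
}

# true VAF of one variant at months m before MM, given its origin timepoint
# (origin_months, v_origin) and MM value vaf_mm
true_vaf_curve <- function(m, origin_months, v_origin, vaf_mm, model) {
  v <- numeric(length(m))
  present <- m <= origin_months
  if (origin_months == 0) {
    v[m == 0] <- vaf_mm
    return(v)
  }
  frac <- 1 - m[present] / origin_months  # 0 at origin, 1 at MM
  if (model == "stepwise") {
    v[present] <- v_origin + (vaf_mm - v_origin) * frac
  } else {
    lo <- stats::qlogis(v_origin); hi <- stats::qlogis(vaf_mm)
    v[present] <- stats::plogis(lo + (hi - lo) * frac)
  }
  v
}

#' Simulate a serial-sample back-tracking cohort
#'
#' Generates the full study structure from a [sim_config()]: sample metadata,
#' per-position allele counts for every sample at every simulated variant
#' position (error-only in samples whose patient does not carry the variant,
#' and in the unrelated background samples), MM-phase variant-call records
#' for variants whose observed MM VAF and depth pass the default filter
#' thresholds, and the latent ground truth.
#'
#' Read counts at a position follow `Binomial(depth, v + e * (1 - v))` where
#' `v` is the true clone VAF in that sample and `e` the position's error
#' rate; depths are overdispersed around the sequencing mode's mean.
#' Identical seeds reproduce the cohort exactly.
#'
#' @param config a [sim_config()]
#' @return list with elements
#'   \describe{
#'     \item{samples}{sample table (see [validate_samples()])}
#'     \item{counts}{allele-count table: `sample_id`, `chrom`, `pos`, `ref`,
#'       `alt`, `ref_count`, `alt_count`}
#'     \item{calls}{MM-phase variant calls (one row per variant passing the
#'       depth/VAF thresholds at its MM sample), with `patient_id`}
#'     \item{truth}{list of `variants` (per-variant latent parameters incl.
#'       `error_rate`, `vaf_mm`, `origin_months`,
#'       `true_first_detectable_months`) and `true_vaf` (per sample x variant
#'       true clone VAF)}
#'     \item{config}{the configuration used}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 3, seed = 7))
#' head(cohort$counts)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  panel <- load_panel_fixture()
  pids <- sprintf("P%02d", seq_len(config$n_patients))

  ## -- samples ------------------------------------------------------------
  sample_rows <- list()
  for (pid in pids) {
    n_tp <- sample(seq(config$timepoints_min, config$timepoints_max), 1L)
    n_pre <- n_tp - 1L
    months <- sort(sample(seq(config$months_min, config$months_max), n_pre),
                   decreasing = TRUE)
    stage <- rep("MGUS", n_pre)
    if (n_pre >= 2L && runif(1) < 0.3) stage[n_pre] <- "SMM"
    sample_rows[[pid]] <- tibble(
      sample_id = sprintf("%s_T%02d", pid, seq_len(n_tp)),
      patient_id = pid,
      stage = c(stage, "MM"),
      months_before_mm = c(months, 0L),
      seq_mode = "standard"
    )
  }
  bg <- tibble(
    sample_id = sprintf("BG%02d", seq_len(config$n_background_samples)),
    patient_id = sprintf("BGP%02d", seq_len(config$n_background_samples)),
    stage = "background", months_before_mm = 0L, seq_mode = "standard"
  )
  samples <- dplyr::bind_rows(dplyr::bind_rows(sample_rows), bg)
  validate_samples(samples)

  ## -- variants and ground truth ------------------------------------------
  n_var <- rpois(config$n_patients, config$mean_variants_per_patient)
  total <- sum(n_var)
  bases <- c("A", "C", "G", "T")
  variants <- tibble(
    patient_id = rep(pids, n_var),
    chrom = paste0("chr", sample(1:22, total, replace = TRUE)),
    pos = sample.int(2e8L, total),  # collisions practically impossible
    ref = sample(bases, total, replace = TRUE),
    gene = sample(panel$genes, total, replace = TRUE),
    consequence = sample(c("missense", "stop_gain", "frameshift", "splice_site"),
                         total, replace = TRUE, prob = c(0.75, 0.10, 0.08, 0.07)),
    classification = sample(c("VUS", "likely_pathogenic", "pathogenic"),
                            total, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  )
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(bases, r), 1L), character(1))
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  variants$vaf_mm <- runif(total, config$vaf_mm_min, config$vaf_mm_max)
  variants$precursor_absent <- runif(total) < config$fraction_precursor_absent
  variants$error_rate <- if (config$error_rate_mean == 0) {
    rep(0, total)  # error-free sequencing, used in calibration checks
  } else {
    rbeta(total, shape1 = config$error_rate_shape,
          shape2 = config$error_rate_shape * (1 - config$error_rate_mean) /
            config$error_rate_mean)
  }

  variants$origin_months <- 0L
  variants$v_origin <- variants$vaf_mm
  for (i in seq_len(nrow(variants))) {
    pre <- sample_rows[[variants$patient_id[i]]]
    pre <- pre$months_before_mm[pre$months_before_mm > 0]
    if (!variants$precursor_absent[i]) {
      variants$origin_months[i] <- if (length(pre) == 1L) pre else sample(pre, 1L)
      variants$v_origin[i] <- variants$vaf_mm[i] *
        runif(1, config$origin_vaf_frac_min, 1)
    }
  }

  ## -- true VAF per sample x variant --------------------------------------
  if (total > 0L) {
    grid <- tidyr::crossing(samples[, c("sample_id", "patient_id",
                                        "months_before_mm")],
                            variants[, c("key", "patient_id")] |>
                              dplyr::rename(variant_patient = "patient_id"))
    grid$true_vaf <- 0
    own <- grid$patient_id == grid$variant_patient
    if (any(own)) {
      vi <- match(grid$key[own], variants$key)
      grid$true_vaf[own] <- mapply(
        function(m, i) true_vaf_curve(m, variants$origin_months[i],
                                      variants$v_origin[i], variants$vaf_mm[i],
                                      config$growth_model),
        grid$months_before_mm[own], vi)
    }
    true_vaf <- grid[, c("sample_id", "key", "true_vaf")]
  } else {
    true_vaf <- tibble(sample_id = character(), key = character(),
                       true_vaf = numeric())
  }

  ## -- observed allele counts ---------------------------------------------
  if (total > 0L) {
    cnt <- dplyr::left_join(true_vaf, variants[, c("key", "chrom", "pos",
                                                   "ref", "alt", "error_rate")],
                            by = "key")
    dp <- draw_depth(nrow(cnt), config$depth_standard,
                     config$depth_dispersion)
    p <- cnt$true_vaf + cnt$error_rate * (1 - cnt$true_vaf)
    nalt <- rbinom(nrow(cnt), dp, p)
    counts <- tibble(sample_id = cnt$sample_id, chrom = cnt$chrom,
                     pos = cnt$pos, ref = cnt$ref, alt = cnt$alt,
                     ref_count = as.integer(dp - nalt),
                     alt_count = as.integer(nalt))
  } else {
    counts <- tibble(sample_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     ref_count = integer(), alt_count = integer())
  }

  ## -- MM-phase variant calls ---------------------------------------------
  mm_samples <- samples$sample_id[samples$stage == "MM"]
  mm_ids <- setNames(mm_samples, samples$patient_id[samples$stage == "MM"])
  calls <- tibble(patient_id = character(), sample_id = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), depth = integer(), alt_count = integer(),
                  vaf = numeric(), consequence = character(),
                  classification = character(), gene = character())
  if (total > 0L) {
    mm_cnt <- counts[counts$sample_id %in% mm_samples, ]
    mm_cnt <- dplyr::inner_join(
      mm_cnt, variants[, c("key", "chrom", "pos", "ref", "alt", "patient_id",
                           "gene", "consequence", "classification")],
      by = c("chrom", "pos", "ref", "alt"))
    own <- mm_cnt$sample_id == mm_ids[mm_cnt$patient_id]
    mm_cnt <- mm_cnt[own, ]
    depth <- mm_cnt$ref_count + mm_cnt$alt_count
    vaf <- mm_cnt$alt_count / depth
    pass <- depth > 30L & vaf >= 0.01
    calls <- tibble(patient_id = mm_cnt$patient_id[pass],
                    sample_id = mm_cnt$sample_id[pass],
                    chrom = mm_cnt$chrom[pass], pos = mm_cnt$pos[pass],
                    ref = mm_cnt$ref[pass], alt = mm_cnt$alt[pass],
                    depth = as.integer(depth[pass]),
                    alt_count = mm_cnt$alt_count[pass],
                    vaf = vaf[pass],
                    consequence = mm_cnt$consequence[pass],
                    classification = mm_cnt$classification[pass],
                    gene = mm_cnt$gene[pass])
  }

  variants$true_first_detectable_months <-
    ifelse(variants$precursor_absent, 0L, variants$origin_months)

  list(samples = samples, counts = counts, calls = calls,
       truth = list(variants = variants, true_vaf = true_vaf),
       config = config)
}

#' Resequence selected positions of one sample at deep coverage
#'
#' Draws fresh allele counts for exactly the requested variant positions of
#' one existing sample, at the deep-mode mean depth, from the same latent
#' truth (same true VAF and per-position error rate). The original counts
#' are left untouched.
#'
#' @param sample_id sample to resequence (must exist in the cohort)
#' @param variant_keys character vector of variant keys
#'   (`"chrom:pos:ref:alt"`); may be empty
#' @param cohort a [simulate_cohort()] result
#' @param seed seed for the new draws (default derived from the cohort seed)
#' @return allele-count tibble for the requested (sample, position) pairs
#' @export
resequence_deep <- function(sample_id, variant_keys, cohort,
                            seed = cohort$config$seed + 1L) {
  config <- cohort$config
  truth <- cohort$truth
  if (!sample_id %in% cohort$samples$sample_id) {
    abort(paste0("unknown sample: ", sample_id))
  }
  if (length(variant_keys) == 0L) {
    return(cohort$counts[0, ])
  }
  unknown <- setdiff(variant_keys, truth$variants$key)
  if (length(unknown) > 0L) {
    abort(paste0("unknown position(s): ", paste(unknown, collapse = ", ")))
  }
  tv <- truth$true_vaf[truth$true_vaf$sample_id == sample_id &
                         truth$true_vaf$key %in% variant_keys, ]
  tv <- dplyr::left_join(tv, truth$variants[, c("key", "chrom", "pos", "ref",
                                                "alt", "error_rate")],
                         by = "key")
  sseed <- (as.integer(seed) +
              sum(utf8ToInt(sample_id))) %% 2147483587L
  withr::with_seed(sseed, {
    dp <- draw_depth(nrow(tv), config$depth_deep, config$depth_dispersion)
    p <- tv$true_vaf + tv$error_rate * (1 - tv$true_vaf)
    nalt <- rbinom(nrow(tv), dp, p)
    tibble(sample_id = sample_id, chrom = tv$chrom, pos = tv$pos,
           ref = tv$ref, alt = tv$alt,
           ref_count = as.integer(dp - nalt), alt_count = as.integer(nalt))
  })
}
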