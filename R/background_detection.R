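#' Build the empirical background null for one variant
#'
#' The presence of a low-VAF variant in a sample is judged against its
#' frequency in unrelated bone-marrow samples: `n` samples (default 10) are
#' drawn, seeded and without replacement, from samples belonging to *other*
#' patients that have coverage at the variant position. The null records each
#' background sample's alt-allele frequency, their mean and standard
#' deviation, and the significance threshold `mean + 3 * sd`.
#'
#' A background sample with coverage but zero alt reads contributes frequency
#' 0; samples with no reads at the position are ineligible.
#'
#' @param variant list or one-row data frame with `chrom`, `pos`, `ref`, `alt`
#' @param counts allele-count table: `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`
#' @param samples sample table mapping `sample_id` to `patient_id`
#' @param exclude_patient patient whose samples may never enter the panel
#'   (all samples of the tested patient, not just the tested sample)
#' @param n background panel size (default 10)
#' @param seed integer seed for the draw; the panel is reproducible per
#'   variant for a given seed
#' @param n_sd number of standard deviations above the mean (default 3)
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population SD)
#' @param allow_smaller permit a panel smaller than `n` when fewer eligible
#'   samples exist (recorded in the result) instead of erroring
#' @return object of class `background_null`: list with `variant` (key
#'   string), `sample_ids`, `freqs`, `mean`, `sd`, `threshold`, `n`,
#'   `n_requested`, `n_sd`
#' @export
build_background_null <- function(variant, counts, samples, exclude_patient,
                                  n = 10L, seed = 1L, n_sd = 3,
                                  sd_denominator = c("n-1", "n"),
                                  allow_smaller = FALSE) {
  sd_denominator <- match.arg(sd_denominator)
  key <- variant_key(variant$chrom, variant$pos, variant$ref, variant$alt)
  at_pos <- counts[counts$chrom == variant$chrom & counts$pos == variant$pos &
                     counts$ref == variant$ref & counts$alt == variant$alt, ]
  pat <- samples$patient_id[match(at_pos$sample_id, samples$sample_id)]
  eligible <- at_pos[!is.na(pat) & pat != exclude_patient &
                       (at_pos$ref_count + at_pos$alt_count) > 0L, ]
  if (nrow(eligible) < n && !allow_smaller) {
    abort(paste0("only ", nrow(eligible), " eligible background samples for ",
                 key, " (need ", n, "); set allow_smaller = TRUE to proceed"))
  }
  n_use <- min(n, nrow(eligible))
  if (n_use == 0L) abort(paste0("no eligible background samples for ", key))
  # per-variant seed so panels are reproducible regardless of call order
  vseed <- (as.integer(seed) +
              sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))) %% 2147483587L
  idx <- withr::with_seed(vseed, sample.int(nrow(eligible), n_use))
  chosen <- eligible[idx, ]
  freqs <- allele_frequency(chosen$ref_count, chosen$alt_count)
  m <- mean(freqs)
  s <- if (length(freqs) < 2L) 0 else sd(freqs)
  if (sd_denominator == "n" && length(freqs) >= 1L) {
    s <- sqrt(mean((freqs - m)^2))
  }
  structure(list(variant = key, sample_ids = chosen$sample_id, freqs = freqs,
                 mean = m, sd = s, threshold = m + n_sd * s,
                 n = n_use, n_requested = as.integer(n), n_sd = n_sd),
            class = "background_null")
}

#' @export
print.background_null <- function(x, ...) {
  cat("<background_null> ", x$variant, "\n",
      "  n = ", x$n, "  mean = ", signif(x$mean, 4),
      "  sd = ", signif(x$sd, 4),
      "  threshold = ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Test whether a variant is significantly present in one sample
#'
#' The candidate's alt-allele frequency must be strictly greater than the
#' background threshold (`mean + 3 * sd` of the unrelated-sample
#' frequencies), and at least `min_alt_reads` reads must support the alt
#' allele. The read-support guard is the programmatic stand-in for manual
#' inspection of the alignments: without it a noise-free background (all
#' frequencies zero) would declare a single stray read significant.
#'
#' @param count one-row allele-count record for the candidate sample at the
#'   variant position (`sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`)
#' @param null a [build_background_null()] result for the same variant
#' @param min_alt_reads minimum supporting reads (default 3)
#' @param mode sequencing mode of the candidate counts
#' @return one-row tibble (class also `detection_result`): `sample_id`,
#'   `variant`, `candidate_freq`, `candidate_alt_count`, `candidate_depth`,
#'   `null_mean`, `null_sd`, `threshold`, `significant`, `mode`, `reason`
#' @export
test_presence <- function(count, null, min_alt_reads = 3L,
                          mode = c("standard", "deep")) {
  mode <- match.arg(mode)
  stopifnot(inherits(null, "background_null"))
  key <- variant_key(count$chrom, count$pos, count$ref, count$alt)
  if (!identical(key, null$variant)) {
    abort(paste0("variant key mismatch: counts are for ", key,
                 " but null was built for ", null$variant))
  }
  depth <- count$ref_count + count$alt_count
  freq <- if (depth > 0L) count$alt_count / depth else NA_real_
  if (depth == 0L) {
    significant <- FALSE
    reason <- "no_coverage"
  } else if (freq > null$threshold && count$alt_count >= min_alt_reads) {
    significant <- TRUE
    reason <- "above_threshold"
  } else if (freq > null$threshold) {
    significant <- FALSE
    reason <- "insufficient_alt_support"
  } else {
    significant <- FALSE
    reason <- "below_threshold"
  }
  out <- tibble(
    sample_id = count$sample_id, variant = key,
    candidate_freq = freq,
    candidate_alt_count = as.integer(count$alt_count),
    candidate_depth = as.integer(depth),
    null_mean = null$mean, null_sd = null$sd, threshold = null$threshold,
    significant = significant, mode = mode, reason = reason
  )
  class(out) <- c("detection_result", class(out))
  out
}

#' Back-track every MM variant through every precursor sample
#'
#' For each tracked variant of each patient, builds the background null from
#' unrelated samples and tests the variant's presence in each of the
#' patient's precursor samples.
#'
#' @param variants tibble of tracked variants with `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt` (typically the [filter_calls()] output plus
#'   `patient_id`)
#' @param counts allele-count table (see [build_background_null()])
#' @param samples sample table
#' @param n_background,min_alt_reads,seed,... passed to
#'   [build_background_null()] / [test_presence()]
#' @param mode label recorded on the results
#' @return tibble of detection results, one row per (precursor sample,
#'   variant) pair, with `patient_id` attached
#' @export
backtrack_variants <- function(variants, counts, samples, n_background = 10L,
                               min_alt_reads = 3L, seed = 1L,
                               mode = "standard", ...) {
  res <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    null <- build_background_null(v, counts, samples,
                                  exclude_patient = v$patient_id,
                                  n = n_background, seed = seed, ...)
    pre <- samples[samples$patient_id == v$patient_id &
                     samples$months_before_mm > 0, ]
    rows <- vector("list", nrow(pre))
    for (j in seq_len(nrow(pre))) {
      cnt <- counts[counts$sample_id == pre$sample_id[j] &
                      counts$chrom == v$chrom & counts$pos == v$pos &
                      counts$ref == v$ref & counts$alt == v$alt, ]
      if (nrow(cnt) == 0L) {
        cnt <- tibble(sample_id = pre$sample_id[j], chrom = v$chrom,
                      pos = v$pos, ref = v$ref, alt = v$alt,
                      ref_count = 0L, alt_count = 0L)
      }
      rows[[j]] <- test_presence(cnt[1, ], null, min_alt_reads, mode = mode)
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out)) out$patient_id <- v$patient_id
    res[[i]] <- out
  }
  dplyr::bind_rows(res)
}

#' Plan deep-resequencing re-tests
#'
#' After standard-mode back-tracking, every precursor sample in which at
#' least one of its patient's MM variants was *not* significantly detected is
#' selected for deeper sequencing, together with exactly those non-significant
#' variant keys. Pairs already significant in standard mode are never
#' re-tested.
#'
#' @param detections detection-result table from [backtrack_variants()]
#'   (standard mode), with `patient_id`
#' @return tibble with one row per (sample, variant) to re-test:
#'   `patient_id`, `sample_id`, `variant`
#' @export
plan_deep_retests <- function(detections) {
  if (nrow(detections) == 0L) {
    return(tibble(patient_id = character(), sample_id = character(),
                  variant = character()))
  }
  miss <- detections[!detections$significant, c("patient_id", "sample_id", "variant")]
  as_tibble(miss[order(miss$patient_id, miss$sample_id, miss$variant), ])
}

#' Fraction of targeted positions covered above depth thresholds
#'
#' Run-level QC: for each threshold `t`, the fraction of positions whose
#' depth is strictly greater than `t` reads.
#'
#' @param depths non-empty numeric vector of per-position depths
#' @param thresholds depth cutoffs (default 30, 150, 300 reads)
#' @return named numeric vector of fractions, non-increasing in the threshold
#' @export
#' @examples
#' coverage_breadth(c(10, 100, 200, 400))
coverage_breadth <- function(depths, thresholds = c(30, 150, 300)) {
  if (length(depths) == 0L) abort("depth vector must be non-empty")
  out <- vapply(thresholds, function(t) mean(depths > t), numeric(1))
  names(out) <- paste0(">", thresholds)
  out
}
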