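test_that("background null reproduces hand-computed mean, SD and threshold", {
  # 11 unrelated samples with known frequencies; panel of 10 drawn from them
  freqs <- c(rep(0.001, 9), 0.011)
  depths <- rep(1000L, 10)
  alts <- as.integer(round(freqs * 1000))
  counts <- mk_counts(paste0("bg", 1:10), alts, depths)
  samples <- mk_samples(paste0("bg", 1:10))
  null <- build_background_null(mk_variant(), counts, samples,
                                exclude_patient = "someone_else", n = 10)
  expect_equal(null$n, 10L)
  expect_equal(sort(null$freqs), sort(freqs))
  expect_equal(null$mean, mean(freqs))
  expect_equal(null$sd, sd(freqs))               # n-1 denominator
  expect_equal(null$threshold, mean(freqs) + 3 * sd(freqs))
  # hand arithmetic for this vector
  expect_equal(null$mean, 0.002)
  expect_equal(null$sd, sqrt(sum((freqs - 0.002)^2) / 9))
})

test_that("noise-free background gives a zero threshold", {
  counts <- mk_counts(paste0("bg", 1:10), rep(0L, 10), rep(500L, 10))
  samples <- mk_samples(paste0("bg", 1:10))
  null <- build_background_null(mk_variant(), counts, samples, "pX", n = 10)
  expect_equal(null$mean, 0)
  expect_equal(null$sd, 0)
  expect_equal(null$threshold, 0)
})

test_that("samples of the tested patient never enter the background panel", {
  counts <- mk_counts(c(paste0("bg", 1:10), "own1", "own2"),
                      rep(0L, 12), rep(500L, 12))
  samples <- mk_samples(c(paste0("bg", 1:10), "own1", "own2"),
                        patient_ids = c(paste0("p", 1:10), "pt", "pt"))
  for (seed in 1:5) {
    null <- build_background_null(mk_variant(), counts, samples,
                                  exclude_patient = "pt", n = 10, seed = seed)
    expect_false(any(c("own1", "own2") %in% null$sample_ids))
  }
  # zero-depth samples are ineligible
  counts2 <- counts
  counts2[1, c("ref_count", "alt_count")] <- list(0L, 0L)
  expect_error(build_background_null(mk_variant(), counts2, samples,
                                     exclude_patient = "pt", n = 10),
               "eligible")
  null2 <- build_background_null(mk_variant(), counts2, samples,
                                 exclude_patient = "pt", n = 10,
                                 allow_smaller = TRUE)
  expect_equal(null2$n, 9L)
})

test_that("presence test applies the strict 3-SD rule with a read guard", {
  samples <- mk_samples(paste0("bg", 1:10))
  zero_null <- build_background_null(
    mk_variant(), mk_counts(paste0("bg", 1:10), rep(0L, 10), rep(500L, 10)),
    samples, "pt", n = 10)

  # zero evidence is never significant
  r0 <- test_presence(mk_counts("cand", 0L, 500L)[1, ], zero_null)
  expect_false(r0$significant)
  expect_equal(r0$reason, "below_threshold")

  # 3 reads of 600 against a noise-free null: significantly detected
  r3 <- test_presence(mk_counts("cand", 3L, 600L)[1, ], zero_null)
  expect_true(r3$significant)
  expect_equal(r3$reason, "above_threshold")

  # below the read guard the same frequency is not called
  r2 <- test_presence(mk_counts("cand", 2L, 600L)[1, ], zero_null)
  expect_false(r2$significant)
  expect_equal(r2$reason, "insufficient_alt_support")

  # frequency exactly at the threshold fails the strict inequality:
  # all-equal background (2/1000 each) -> sd 0, threshold = mean = 0.002
  null <- build_background_null(
    mk_variant(),
    mk_counts(paste0("bg", 1:10), rep(2L, 10), rep(1000L, 10)),
    samples, "pt", n = 10)
  expect_equal(null$threshold, 0.002)
  exact <- test_presence(mk_counts("cand", 4L, 2000L)[1, ], null)
  expect_equal(exact$candidate_freq, null$threshold)
  expect_false(exact$significant)
  expect_equal(exact$reason, "below_threshold")
  above <- test_presence(mk_counts("cand", 5L, 2000L)[1, ], null)
  expect_true(above$significant)

  # no coverage
  rnc <- test_presence(mk_counts("cand", 0L, 0L)[1, ], zero_null)
  expect_equal(rnc$reason, "no_coverage")
  expect_false(rnc$significant)

  # key mismatch is an error
  other <- mk_counts("cand", 3L, 600L, pos = 101L)[1, ]
  expect_error(test_presence(other, zero_null), "mismatch")
})

test_that("significance is monotone in alt count at fixed depth", {
  samples <- mk_samples(paste0("bg", 1:10))
  for (seed in 1:10) {
    withr::with_seed(seed, {
      alts <- rbinom(10, 800, 0.002)
      null <- build_background_null(
        mk_variant(), mk_counts(paste0("bg", 1:10), alts, rep(800L, 10)),
        samples, "pt", n = 10, seed = seed)
      sig <- vapply(0:25, function(a)
        test_presence(mk_counts("c", a, 800L)[1, ], null)$significant,
        logical(1))
      # once significant, more alt reads never flip it back
      expect_true(all(diff(sig) >= 0))
    })
  }
})

test_that("decision with an all-equal background is seed-invariant", {
  counts <- mk_counts(paste0("bg", 1:15), rep(1L, 15), rep(1000L, 15))
  samples <- mk_samples(paste0("bg", 1:15))
  cand <- mk_counts("cand", 5L, 1000L)[1, ]
  decisions <- vapply(1:8, function(s) {
    null <- build_background_null(mk_variant(), counts, samples, "pt",
                                  n = 10, seed = s)
    test_presence(cand, null)$significant
  }, logical(1))
  expect_equal(length(unique(decisions)), 1L)
  # and the same seed always draws the same panel
  n1 <- build_background_null(mk_variant(), counts, samples, "pt", n = 10,
                              seed = 3)
  n2 <- build_background_null(mk_variant(), counts, samples, "pt", n = 10,
                              seed = 3)
  expect_identical(n1$sample_ids, n2$sample_ids)
})

test_that("population-SD option narrows the threshold", {
  freqs <- c(rep(0.001, 9), 0.011)
  counts <- mk_counts(paste0("bg", 1:10), as.integer(freqs * 1000),
                      rep(1000L, 10))
  samples <- mk_samples(paste0("bg", 1:10))
  n1 <- build_background_null(mk_variant(), counts, samples, "pt", n = 10)
  n2 <- build_background_null(mk_variant(), counts, samples, "pt", n = 10,
                              sd_denominator = "n")
  expect_lt(n2$sd, n1$sd)
  expect_equal(n2$sd, sqrt(mean((freqs - mean(freqs))^2)))
})

test_that("deep-retest plan contains exactly the non-significant pairs", {
  det <- tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2"),
    sample_id = c("s1", "s2", "s1", "s3"),
    variant = c("chr1:1:A:T", "chr1:1:A:T", "chr2:2:C:G", "chr3:3:G:A"),
    significant = c(FALSE, TRUE, TRUE, FALSE))
  plan <- plan_deep_retests(det)
  expect_equal(nrow(plan), 2L)
  expect_setequal(paste(plan$sample_id, plan$variant),
                  c("s1 chr1:1:A:T", "s3 chr3:3:G:A"))
  # all significant -> empty plan; empty input -> empty plan
  expect_equal(nrow(plan_deep_retests(det[det$significant, ])), 0L)
  expect_equal(nrow(plan_deep_retests(det[0, ])), 0L)
})

test_that("coverage breadth counts strictly-greater positions per threshold", {
  expect_equal(unname(coverage_breadth(rep(1000, 5))), c(1, 1, 1))
  expect_equal(unname(coverage_breadth(c(10, 100, 200, 400))),
               c(0.75, 0.5, 0.25))
  b <- coverage_breadth(c(10, 100, 200, 400))
  expect_true(all(diff(b) <= 0))
  expect_error(coverage_breadth(numeric(0)), "non-empty")
  # boundary: depth equal to the threshold does not count
  expect_equal(unname(coverage_breadth(c(30, 31), thresholds = 30)), 0.5)
})
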