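gt13 <- make_ground_truth(3, seed = 1)

test_that("sampled z-scores follow the noise-free trajectory exactly", {
  expect_equal(unname(sample_zscores(gt13, 1, 0, 0, 1)), rep(0, 13))
  expect_equal(unname(sample_zscores(gt13, 2, 39, 0, 1)), rep(3, 13))
  for (k in c(3, 11, 26)) {
    z <- sample_zscores(gt13, 1, k, 0, seed = 2)
    mu <- vapply(1:13, function(b) {
      oracle_expected_z(gt13$sequences[[1]], k, b, 13)
    }, numeric(1))
    expect_equal(unname(z), mu, tolerance = 1e-12)
  }
  expect_error(sample_zscores(gt13, 9, 0, 0, 1), "subtype")
})

test_that("cohort generation is seeded, typed, and empty-safe", {
  c0 <- generate_cohort(gt13, 0, cohort_config(), seed = 1)
  expect_equal(nrow(c0), 0)
  a <- generate_cohort(gt13, 60, cohort_config(), seed = 5)
  b <- generate_cohort(gt13, 60, cohort_config(), seed = 5)
  expect_identical(a, b)
  d <- generate_cohort(gt13, 60, cohort_config(), seed = 6)
  expect_false(identical(a, d))
  expect_true(all(a$mmse >= 0 & a$mmse <= 30))
  expect_true(all(as.matrix(a[, gt13$panel$names]) > 0))
  expect_true(all(a$true_stage >= 0 & a$true_stage <= 39))
})

test_that("subtype frequencies match the configured fractions", {
  co <- generate_cohort(gt13, 2000, cohort_config(), seed = 11)
  counts <- tabulate(co$true_subtype, nbins = 3)
  chi <- chisq.test(counts, p = gt13$fractions)
  expect_gt(chi$p.value, 0.001)
  # law of large numbers at n = 5000: within 3 standard errors
  co5 <- generate_cohort(gt13, 5000, cohort_config(), seed = 12)
  freq <- tabulate(co5$true_subtype, nbins = 3) / 5000
  se <- sqrt(gt13$fractions * (1 - gt13$fractions) / 5000)
  expect_true(all(abs(freq - gt13$fractions) < 3 * se))
})

test_that("hidden z-scores of a noise-free cohort satisfy the trajectory", {
  co <- generate_cohort(gt13, 40, cohort_config(noise_sd = 0), seed = 3)
  for (i in seq_len(10)) {
    mu <- vapply(1:13, function(b) {
      oracle_expected_z(gt13$sequences[[co$true_subtype[i]]],
                        co$true_stage[i], b, 13)
    }, numeric(1))
    expect_equal(unname(unlist(co[i, paste0("true_z_", gt13$panel$names)])),
                 mu, tolerance = 1e-12)
  }
})

test_that("MMSE declines with true stage in expectation", {
  co <- generate_cohort(gt13, 3000, cohort_config(stage_sampling = "uniform"),
                        seed = 8)
  means <- tapply(co$mmse, co$true_stage, mean)
  fit <- lm(as.numeric(means) ~ as.numeric(names(means)))
  expect_lt(coef(fit)[2], 0)
})

test_that("follow-up drifts stages forward without changing subtype", {
  co <- generate_cohort(gt13, 400, cohort_config(), seed = 4)
  f0 <- advance_followup(co, 0, gt13, seed = 5)
  expect_equal(f0$true_stage, co$true_stage)
  f12 <- advance_followup(co, 12, gt13, seed = 5)
  expect_identical(f12$true_subtype, co$true_subtype)
  expect_equal(f12$visit_month, rep(12L, nrow(co)))
  expect_true(all(f12$true_stage >= 0 & f12$true_stage <= 39))
  co$true_stage <- NULL
  expect_error(advance_followup(co, 12, gt13, seed = 1), "synthetic")
})

test_that("mean 12-month stage drift matches the configured 0.8", {
  # mid-stage subjects, away from the grid boundaries that clamp the draw
  gt <- make_ground_truth(1, seed = 2)
  co <- generate_cohort(gt, 5000, cohort_config(stage_sampling = "uniform"),
                        seed = 9)
  mid <- co$true_stage >= 8 & co$true_stage <= 31
  f12 <- advance_followup(co, 12, gt, seed = 10)
  drift <- f12$true_stage[mid] - co$true_stage[mid]
  expect_lt(abs(mean(drift) - 0.8), 0.1)
  expect_lt(abs(sd(drift) - 1.5), 0.2)
})

test_that("conversion labelling marks threshold-crossing amyloid MCI", {
  co <- generate_cohort(gt13, 800, cohort_config(), seed = 21)
  f12 <- advance_followup(co, 12, gt13, seed = 22)
  lab <- label_conversions(co, f12, gt13, threshold = 12, p_nonamyloid = 0,
                           seed = 23)
  expect_true(all(lab$longitudinal[lab$diagnosis != "MCI"] == "none"))
  pm <- lab$longitudinal == "pMCI"
  expect_true(all(f12$true_stage[pm] >= 12))
  expect_true(all(lab$csf_abeta[pm] < 192, na.rm = TRUE))
  expect_true(any(pm) && any(lab$longitudinal == "sMCI"))
})
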