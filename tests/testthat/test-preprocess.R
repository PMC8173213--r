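make_flat_cohort <- function(n = 40, seed = 1) {
  # simple cohort with hand-constructed volumes for closed-form checks
  set.seed(seed)
  p <- default_panel()
  vols <- matrix(5000, n, 13, dimnames = list(NULL, p$names))
  data.frame(id = sprintf("s%03d", 1:n), cohort = "train",
             diagnosis = sample(c("CN", "MCI", "AD"), n, replace = TRUE),
             longitudinal = "none", vols,
             age = runif(n, 60, 85), sex = sample(c("F", "M"), n, TRUE),
             education = round(runif(n, 8, 20)),
             apoe4 = rbinom(n, 1, 0.4), tiv = rnorm(n, 1.4e6, 1e5),
             mmse = 29L, csf_abeta = rnorm(n, 200, 40), visit_month = 0L,
             check.names = FALSE)
}

test_that("amyloid-negative selection is strict, CN-only, NA-safe", {
  co <- data.frame(id = c("a", "b", "c", "d", "e"),
                   diagnosis = c("CN", "CN", "MCI", "CN", "CN"),
                   csf_abeta = c(200, 192, 300, NA, 150))
  expect_equal(select_amyloid_negative_controls(co), "a")
  co$csf_abeta[1] <- 100
  expect_error(select_amyloid_negative_controls(co), "reference unusable")
})

test_that("covariate regression recovers an exact linear age effect", {
  co <- make_flat_cohort()
  co$hippocampus <- 5000 - 20 * co$age
  model <- fit_covariate_adjustment(co, default_panel())
  expect_equal(unname(model$coefficients["hippocampus", "age"]), -20,
               tolerance = 1e-6)
  # other regions were constant: every coefficient vanishes
  expect_lt(max(abs(model$coefficients["fusiform", ])), 1e-8)
  model2 <- fit_covariate_adjustment(co, default_panel())
  expect_identical(model$coefficients, model2$coefficients)

  # with residual variation present, OLS residualization is exactly
  # orthogonal to every covariate in-sample
  co$hippocampus <- co$hippocampus + rnorm(nrow(co), sd = 50)
  model3 <- fit_covariate_adjustment(co, default_panel())
  adj <- apply_adjustment(model3, co)
  expect_lt(abs(cor(adj[, "hippocampus"], co$age)), 1e-6)
})

test_that("adjustment leaves reference-mean subjects untouched", {
  co <- make_flat_cohort(seed = 2)
  co$entorhinal <- 2000 - 15 * co$age + 80 * co$apoe4
  model <- fit_covariate_adjustment(co, default_panel())
  ref <- model$reference_means
  probe <- co[1, ]
  probe$age <- ref["age"]; probe$sex <- if (ref["sex"] > 0.5) "M" else "F"
  probe$education <- ref["education"]; probe$apoe4 <- ref["apoe4"]
  probe$tiv <- ref["tiv"]
  adj <- apply_adjustment(model, probe)
  # sex is binary so only the remaining covariates are exactly at reference
  expected <- probe$entorhinal -
    model$coefficients["entorhinal", "sex"] *
    (as.numeric(probe$sex == "M") - ref["sex"])
  expect_equal(unname(adj[1, "entorhinal"]), unname(expected),
               tolerance = 1e-8)

  zero <- model
  zero$coefficients[] <- 0
  expect_equal(unname(apply_adjustment(zero, co)[, "precuneus"]),
               co$precuneus)
})

test_that("rank-deficient designs are reported with the offending covariate", {
  co <- make_flat_cohort()
  co$education <- 12 # constant column aliases the intercept
  expect_error(fit_covariate_adjustment(co, default_panel()),
               "rank-deficient.*education")
})

test_that("rows with missing covariates are flagged and excluded", {
  co <- make_flat_cohort()
  co$age[3] <- NA
  model <- fit_covariate_adjustment(co, default_panel())
  adj <- apply_adjustment(model, co)
  expect_true(attr(adj, "excluded")[3])
  expect_true(all(is.na(adj[3, ])))
  expect_false(any(attr(adj, "excluded")[-3]))
})

test_that("z-scores are signed so abnormality is positive", {
  p <- default_panel()
  stats <- structure(list(mean = setNames(rep(100, 13), p$names),
                          sd = setNames(rep(10, 13), p$names), n = 50),
                     class = "control_stats")
  vals <- matrix(100, 2, 13, dimnames = list(NULL, p$names))
  vals[2, "hippocampus"] <- 90   # one control-SD below the mean
  vals[2, "ventricles"] <- 110   # one control-SD above the mean
  Z <- compute_zscores(vals, stats, p)
  expect_equal(unname(Z[1, ]), rep(0, 13))
  expect_equal(unname(Z[2, "hippocampus"]), 1)
  expect_equal(unname(Z[2, "ventricles"]), 1)
})

test_that("reference subjects z-score to mean 0 and SD 1", {
  gt <- make_ground_truth(3, seed = 2)
  co <- generate_cohort(gt, 300, cohort_config(), seed = 14)
  model <- fit_covariate_adjustment(co, gt$panel)
  adj <- apply_adjustment(model, co)
  ref_rows <- co$diagnosis == "CN"
  st <- control_stats(adj, ref_rows)
  Z <- compute_zscores(adj, st, gt$panel)
  zr <- Z[ref_rows, ]
  expect_lt(max(abs(colMeans(zr))), 1e-10)
  expect_lt(max(abs(apply(zr, 2, sd) - 1)), 1e-10)
})

test_that("CSF rescaling matches the moment formula and keeps NAs", {
  expect_equal(rescale_csf(150, 150, 25, 200, 50), 200)
  expect_equal(rescale_csf(175, 150, 25, 200, 50), 250)
  x <- c(100, NA, 200)
  expect_equal(rescale_csf(x, 150, 50, 150, 50), x) # identity
  expect_true(is.na(rescale_csf(x, 150, 50, 180, 40)[2]))
  expect_error(rescale_csf(x, 150, 0, 180, 40), "degenerate")
})

test_that("noise-free generator round-trip recovers hidden z to 1e-6", {
  gt <- make_ground_truth(3, seed = 3)
  co <- generate_cohort(gt, 400, cohort_config(noise_sd = 0), seed = 15)
  # noise-free stage-0 subjects carry pure confounds: exact OLS reference
  ref <- co$true_stage == 0
  expect_gt(sum(ref), 10)
  model <- fit_covariate_adjustment(co, gt$panel, subset = ref)
  # pin the residualization reference point to the generator's, so the
  # truth-referenced control stats apply without an offset
  model$reference_means <- gt$covariate_reference
  adj <- apply_adjustment(model, co)
  Z <- compute_zscores(adj, control_stats_from_truth(gt), gt$panel)
  truth <- as.matrix(co[, paste0("true_z_", gt$panel$names)])
  expect_lt(max(abs(Z - truth)), 1e-6)
  # confounds removed: beyond the disease signal the adjusted volume is the
  # control-scale constant
  noise_part <- adj[, "hippocampus"] +
    gt$control_sd["hippocampus"] * truth[, "true_z_hippocampus"]
  expect_lt(max(abs(noise_part - gt$control_mean["hippocampus"])), 1e-6)
})

test_that("re-adjusting already-adjusted volumes is idempotent", {
  gt <- make_ground_truth(1, seed = 4)
  co <- generate_cohort(gt, 200, cohort_config(), seed = 16)
  model <- fit_covariate_adjustment(co, gt$panel)
  adj <- apply_adjustment(model, co)
  co2 <- co
  co2[gt$panel$names] <- as.data.frame(adj)
  model2 <- fit_covariate_adjustment(co2, gt$panel)
  expect_lt(max(abs(model2$coefficients)), 1e-8)
})
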