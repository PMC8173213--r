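test_that("visual rating rules partition all eight triples", {
  grid <- expand.grid(mta = c(TRUE, FALSE), pa = c(TRUE, FALSE),
                      gcaf = c(TRUE, FALSE))
  cats <- visual_rating_subtype(grid$mta, grid$pa, grid$gcaf)
  expect_false(anyNA(cats))
  # the three quoted rules
  expect_equal(as.character(visual_rating_subtype(TRUE, TRUE, FALSE)),
               "typical")
  expect_equal(as.character(visual_rating_subtype(FALSE, FALSE, FALSE)),
               "minimal")
  expect_equal(as.character(visual_rating_subtype(TRUE, FALSE, FALSE)),
               "limbic-predominant")
  # every triple maps to exactly one category (factor is single-valued by
  # construction; check the expected partition sizes)
  expect_equal(as.vector(table(cats)),
               c(typical = 3, `hippocampal-sparing` = 3,
                 `limbic-predominant` = 1, minimal = 1),
               ignore_attr = TRUE)
})

test_that("subtype consistency counts stable assignments", {
  a0 <- data.frame(id = sprintf("s%d", 1:10),
                   subtype = c(1, 1, 1, 2, 2, 2, 1, 2, 1, 2),
                   stage = 5)
  a1 <- a0
  expect_equal(subtype_consistency(a0, a1)$stable_fraction, 1)
  a2 <- a0; a2$subtype <- 3 - a0$subtype
  expect_equal(subtype_consistency(a0, a2)$stable_fraction, 0)
  a3 <- a0; a3$subtype[c(1, 4)] <- 3 - a3$subtype[c(1, 4)]
  res <- subtype_consistency(a0, a3)
  expect_equal(res$stable_fraction, 0.8)
  expect_equal(sum(res$transitions) - sum(diag(res$transitions)), 2)
  # undefined subtypes drop out
  a4 <- a0; a4$subtype[1] <- NA
  expect_equal(subtype_consistency(a0, a4)$n_compared, 9)
  expect_error(subtype_consistency(a0, data.frame(id = "zz", subtype = 1)),
               "overlapping")
})

test_that("stage-cognition regression reproduces exact linear relations", {
  a <- data.frame(subtype = 1, stage = c(0, 5, 10))
  res <- stage_cognition_fit(a, c(29, 27, 25))
  expect_equal(res$slope, -0.4, tolerance = 1e-12)
  expect_equal(res$r.squared, 1, tolerance = 1e-12)
  resc <- stage_cognition_fit(a, c(25, 25, 25))
  expect_equal(resc$r.squared, 0, tolerance = 1e-12)
  expect_error(stage_cognition_fit(data.frame(subtype = 1, stage = c(1, 1, 2)),
                                   c(1, 2, 3)), "3 distinct stages")
  # per-stage averaging: duplicated stages collapse to their means
  a2 <- data.frame(subtype = 1, stage = c(0, 0, 5, 5, 10, 10))
  res2 <- stage_cognition_fit(a2, c(30, 28, 28, 26, 26, 24))
  expect_equal(res2$slope, -0.4, tolerance = 1e-12)
  expect_equal(res2$r.squared, 1, tolerance = 1e-12)
})

test_that("conversion feature tables encode subtypes and drop missing rows", {
  a <- data.frame(subtype = c(1, 2, 3, NA, 2), stage = c(3, 8, 12, 20, 9))
  X1 <- conversion_features(a, features = "stage")
  expect_equal(colnames(X1), "stage")
  expect_equal(nrow(X1), 5)
  X2 <- conversion_features(a, features = "subtype", n_subtypes = 3)
  expect_equal(colnames(X2), c("subtype2", "subtype3"))
  expect_equal(nrow(X2), 4) # NA-subtype row excluded
  expect_equal(attr(X2, "n_excluded"), 1)
  X3 <- conversion_features(a, mmse = rep(28, 5), abeta = c(1, 2, NA, 4, 5),
                            features = c("stage", "mmse", "abeta"))
  expect_equal(nrow(X3), 4)
  expect_error(conversion_features(a, features = character(0)), "empty")
})

test_that("logistic classifier recovers simulated coefficients within 3 SE", {
  set.seed(99)
  n <- 2000
  x <- rnorm(n)
  p <- plogis(-1 + 0.5 * x)
  y <- ifelse(runif(n) < p, "pMCI", "sMCI")
  X <- cbind(x = x)
  fit <- fit_conversion_classifier(X, y)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$coefficients[1] - (-1)), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] - 0.5), 3 * se[2])
  expect_false(fit$separation)
  refit <- fit_conversion_classifier(X, y)
  expect_identical(fit$coefficients, refit$coefficients)
  # label-independent feature gives a near-zero slope
  set.seed(100)
  y2 <- sample(c("pMCI", "sMCI"), n, replace = TRUE)
  fit2 <- fit_conversion_classifier(X, y2)
  se2 <- summary(fit2$fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(fit2$coefficients["x"]), 3 * se2)
})

test_that("perfect separation is flagged, not fatal", {
  X <- cbind(x = c(-2, -1.5, -1, 1, 1.5, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_conversion_classifier(X, y)
  expect_true(fit$separation)
})

test_that("ROC AUC equals the concordant-pair probability", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_curve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 8), rep(0:1, 4))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  # invariance under strictly monotone transforms
  set.seed(17)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  a1 <- roc_curve(sc, lb)$auc
  expect_equal(roc_curve(exp(sc), lb)$auc, a1)
  expect_equal(roc_curve(qlogis(plogis(sc)), lb)$auc, a1, tolerance = 1e-12)
  # curve points are monotone
  expect_true(all(diff(roc_curve(sc, lb)$fpr) >= 0))
  expect_true(all(diff(roc_curve(sc, lb)$tpr) >= 0))
})

test_that("placement-value AUC equals the rank-sum AUC", {
  set.seed(23)
  for (rep in 1:5) {
    sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- roc_curve(sc, lb)
    expect_equal(sustainr:::delong_placements(r)$auc, r$auc,
                 tolerance = 1e-12)
  }
})

test_that("identical curves give AUC difference 0 and p = 1", {
  set.seed(31)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.5)
  r <- roc_curve(sc, lb)
  res <- delong_compare(r, r, paired = FALSE)
  expect_equal(res$auc_diff, 0)
  expect_equal(res$p.value, 1)
})

test_that("unpaired DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  s1 <- rnorm(80) + rbinom(80, 1, 0.5); l1 <- rbinom(80, 1, 0.5)
  s2 <- rnorm(90); l2 <- rbinom(90, 1, 0.5)
  r1 <- roc_curve(s1, l1); r2 <- roc_curve(s2, l2)
  mine <- delong_compare(r1, r2)
  ref <- pROC::roc.test(pROC::roc(l1, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(l2, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  # identical statistic; pROC maps it through a t reference while the
  # normal reference is used here, so p-values agree only approximately
  expect_equal(mine$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-2)
  expect_equal(mine$auc_a, as.numeric(pROC::auc(pROC::roc(l1, s1, quiet = TRUE,
                                                          direction = "<"))))
})

test_that("group tests match hand computations", {
  res0 <- group_difference_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  tab <- matrix(c(10, 0, 0, 10), 2)
  resc <- group_difference_tests(tab)
  expect_equal(resc$statistic, 20)
  expect_error(group_difference_tests(1:5, rep("a", 5)), "2 groups")
})
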