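#' Select the amyloid-negative control reference
#'
#' The z-scoring reference population is the cognitively normal (CN)
#' subjects whose CSF amyloid-beta 1-42 concentration is strictly greater
#' than the cut-off (default 192 pg/ml, above which a subject is
#' amyloid-negative). Subjects with missing CSF never qualify.
#'
#' @param cohort a cohort table.
#' @param cutoff CSF cut-off in pg/ml (> 0).
#' @return character vector of subject ids.
#' @export
select_amyloid_negative_controls <- function(cohort, cutoff = 192) {
  stopifnot(cutoff > 0)
  sel <- cohort$diagnosis == "CN" & !is.na(cohort$csf_abeta) &
    cohort$csf_abeta > cutoff
  ids <- cohort$id[sel]
  if (length(ids) == 0L) {
    stop("no amyloid-negative CN subjects found; reference unusable")
  }
  ids
}

covariate_design <- function(cohort) {
  cbind(age = cohort$age,
        sex = as.numeric(cohort$sex == "M"),
        education = as.numeric(cohort$education),
        apoe4 = as.numeric(cohort$apoe4),
        tiv = cohort$tiv)
}

#' Fit the covariate adjustment model
#'
#' Ordinary least-squares regression of each region's raw volume on age, sex
#' (male indicator), education years, APOE-e4 carriership and total
#' intracranial volume, the standard multiple-linear-regression volumetric
#' correction. Fitted per cohort; rows with any missing covariate or volume
#' are dropped from the fit.
#'
#' @param cohort a cohort table.
#' @param panel a `sustain_panel`.
#' @param subset optional logical or id vector restricting the fitting rows
#'   (e.g. controls only); the correction is still applied to everyone via
#'   [apply_adjustment()].
#' @return an object of class `adjustment_model`: per-region coefficients and
#'   the reference covariate means of the fitting sample.
#' @export
fit_covariate_adjustment <- function(cohort, panel, subset = NULL) {
  rows <- rep(TRUE, nrow(cohort))
  if (!is.null(subset)) {
    rows <- if (is.logical(subset)) subset else cohort$id %in% subset
  }
  X <- covariate_design(cohort)
  V <- as.matrix(cohort[, panel$names, drop = FALSE])
  ok <- rows & stats::complete.cases(X) & stats::complete.cases(V)
  if (sum(ok) < 6L) {
    stop("need at least 6 complete-covariate subjects to fit the adjustment")
  }
  X <- X[ok, , drop = FALSE]
  V <- V[ok, , drop = FALSE]

  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("rank-deficient covariate design; offending covariate(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrX, V) # (1 + 5) x B

  structure(
    list(panel_names = panel$names,
         intercept = coefs[1L, ],
         coefficients = t(coefs[-1L, , drop = FALSE]), # B x 5
         reference_means = colMeans(X),
         n_fit = sum(ok)),
    class = "adjustment_model"
  )
}

#' Apply a covariate adjustment
#'
#' Residualizes volumes to the model's reference covariate means:
#' `adjusted = raw - sum_j coef_j * (covariate_j - reference_mean_j)`.
#' A subject whose covariates sit exactly at the reference means is
#' unchanged. Rows with missing covariates are returned as NA and flagged in
#' the `"excluded"` attribute so downstream stages can drop them.
#'
#' @param model an `adjustment_model`.
#' @param cohort a cohort table with the model's panel columns.
#' @return numeric matrix (subjects x regions) of adjusted volumes with an
#'   `"excluded"` logical attribute.
#' @export
apply_adjustment <- function(model, cohort) {
  stopifnot(inherits(model, "adjustment_model"))
  if (!all(model$panel_names %in% names(cohort))) {
    stop("cohort lacks panel region columns: ",
         paste(setdiff(model$panel_names, names(cohort)), collapse = ", "))
  }
  X <- covariate_design(cohort)
  V <- as.matrix(cohort[, model$panel_names, drop = FALSE])
  excluded <- !stats::complete.cases(X)
  centered <- sweep(X, 2L, model$reference_means[colnames(X)])
  centered[excluded, ] <- 0
  adjusted <- V - centered %*% t(model$coefficients)
  adjusted[excluded, ] <- NA_real_
  attr(adjusted, "excluded") <- excluded
  adjusted
}

#' Reference statistics of the control population
#'
#' Per-region mean and SD of adjusted volumes over the reference subjects
#' (the training cohort's amyloid-negative CN group in the standard
#' pipeline).
#'
#' @param adjusted adjusted volume matrix from [apply_adjustment()].
#' @param rows logical/integer rows defining the reference subjects.
#' @return an object of class `control_stats`.
#' @export
control_stats <- function(adjusted, rows) {
  ref <- adjusted[rows, , drop = FALSE]
  ref <- ref[stats::complete.cases(ref), , drop = FALSE]
  if (nrow(ref) < 2L) stop("control reference needs at least 2 subjects")
  m <- colMeans(ref)
  s <- apply(ref, 2L, stats::sd)
  if (any(s <= 0)) {
    stop("degenerate control SD (<= 0) for region(s): ",
         paste(colnames(ref)[s <= 0], collapse = ", "))
  }
  structure(list(mean = m, sd = s, n = nrow(ref)), class = "control_stats")
}

#' Control statistics from a synthetic ground truth
#'
#' The generator's own control-scale means and SDs, packaged as a
#' `control_stats`; used in oracle round-trip checks where the data-estimated
#' reference would be degenerate (noise-free cohorts).
#'
#' @param gt a `sustain_truth`.
#' @return a `control_stats`.
#' @export
control_stats_from_truth <- function(gt) {
  structure(list(mean = gt$control_mean, sd = gt$control_sd, n = Inf),
            class = "control_stats")
}

#' Convert adjusted volumes to abnormality z-scores
#'
#' Z-scores are referenced to the control distribution and signed so that
#' abnormality is always positive: atrophy regions score
#' `(control mean - value) / control SD` (smaller = more abnormal) and the
#' expansion region (ventricles) scores `(value - control mean) / control SD`
#' (larger = more abnormal).
#'
#' @param adjusted adjusted volume matrix (subjects x regions).
#' @param stats a `control_stats`.
#' @param panel a `sustain_panel`.
#' @return z-score matrix (subjects x regions).
#' @export
compute_zscores <- function(adjusted, stats, panel) {
  stopifnot(inherits(stats, "control_stats"), all(stats$sd > 0))
  Z <- sweep(adjusted[, panel$names, drop = FALSE], 2L, stats$mean[panel$names])
  Z <- sweep(Z, 2L, stats$sd[panel$names], `/`)
  sweep(Z, 2L, panel$sign, `*`)
}

#' Rescale CSF values between assay scales
#'
#' Linear moment matching for CSF concentrations measured on a different
#' assay: `y = (x - source_mean) / source_sd * target_sd + target_mean`.
#' Missing values stay missing.
#'
#' @param values numeric CSF concentrations (NA allowed).
#' @param source_mean,source_sd moments of the source distribution
#'   (`source_sd > 0`).
#' @param target_mean,target_sd moments of the target (training-set)
#'   distribution.
#' @return rescaled values.
#' @export
rescale_csf <- function(values, source_mean, source_sd, target_mean, target_sd) {
  if (!is.finite(source_sd) || source_sd <= 0) {
    stop("degenerate source SD in CSF rescaling")
  }
  (values - source_mean) / source_sd * target_sd + target_mean
}

#' Full preprocessing of a training/test cohort pair
#'
#' Runs the standard chain: covariate adjustment fitted separately per
#' cohort; the z-scoring reference is always the training cohort's
#' amyloid-negative CN subjects; the test cohort's CSF values (when present)
#' are moment-matched to the training CSF scale so the same cut-off applies.
#' When the test cohort has no usable CSF, rescaling is skipped and CSF is
#' treated as missing-by-design downstream.
#'
#' @param train,test cohort tables (`test` may be NULL).
#' @param panel a `sustain_panel`.
#' @param cutoff amyloid cut-off in pg/ml.
#' @param fit_on `"all"` fits the adjustment on all cohort subjects (default),
#'   `"controls"` on CN subjects only.
#' @return list with z-score matrices, adjustment models, control stats and
#'   the reference id set.
#' @export
preprocess_cohorts <- function(train, test = NULL, panel = default_panel(),
                               cutoff = 192, fit_on = c("all", "controls")) {
  fit_on <- match.arg(fit_on)
  sub_train <- if (fit_on == "controls") train$diagnosis == "CN" else NULL
  model_train <- fit_covariate_adjustment(train, panel, subset = sub_train)
  adj_train <- apply_adjustment(model_train, train)

  control_ids <- select_amyloid_negative_controls(train, cutoff)
  stats <- control_stats(adj_train, train$id %in% control_ids)
  z_train <- compute_zscores(adj_train, stats, panel)
  rownames(z_train) <- train$id

  out <- list(panel = panel, cutoff = cutoff, fit_on = fit_on,
              model_train = model_train, control_ids = control_ids,
              stats = stats, z_train = z_train,
              train_csf_mean = mean(train$csf_abeta, na.rm = TRUE),
              train_csf_sd = stats::sd(train$csf_abeta, na.rm = TRUE))

  if (!is.null(test)) {
    sub_test <- if (fit_on == "controls") test$diagnosis == "CN" else NULL
    model_test <- fit_covariate_adjustment(test, panel, subset = sub_test)
    adj_test <- apply_adjustment(model_test, test)
    z_test <- compute_zscores(adj_test, stats, panel)
    rownames(z_test) <- test$id
    csf_n <- sum(!is.na(test$csf_abeta))
    csf_rescaled <- if (csf_n >= 2L) {
      rescale_csf(test$csf_abeta,
                  mean(test$csf_abeta, na.rm = TRUE),
                  stats::sd(test$csf_abeta, na.rm = TRUE),
                  out$train_csf_mean, out$train_csf_sd)
    } else {
      rep(NA_real_, nrow(test)) # missing-by-design cohorts
    }
    out$model_test <- model_test
    out$z_test <- z_test
    out$test_csf_rescaled <- csf_rescaled
  }
  out
}
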