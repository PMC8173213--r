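#' Sample a z-score vector at a given subtype and stage
#'
#' Draws the model-expected z-score of every panel biomarker at the given
#' stage of the subtype's event sequence, plus independent Gaussian
#' measurement noise. With `noise_sd = 0` the expected trajectory values are
#' returned exactly: all zeros at stage 0 and the maximum abnormality 3 for
#' every biomarker at the final stage.
#'
#' @param gt a `sustain_truth`.
#' @param subtype subtype index (1-based).
#' @param stage integer stage in 0..N.
#' @param noise_sd non-negative noise SD in z-score units.
#' @param seed integer seed.
#' @return numeric z-vector of length B, named by region.
#' @export
sample_zscores <- function(gt, subtype, stage, noise_sd = 1, seed = 1) {
  stopifnot(inherits(gt, "sustain_truth"), noise_sd >= 0)
  if (subtype < 1 || subtype > gt$n_subtypes) stop("invalid subtype index")
  N <- gt$panel$n_events
  stopifnot(stage >= 0, stage <= N)
  pos <- seq_positions(gt$sequences[[subtype]], gt$panel$n_biomarkers)
  mu <- expected_matrix(pos, N)[stage + 1L, ]
  z <- with_local_seed(child_seed(seed, "zscores"), {
    mu + stats::rnorm(length(mu), sd = noise_sd)
  })
  names(z) <- gt$panel$names
  z
}

#' Cohort generator configuration
#'
#' @param cohort_label `"train"` or `"test"` (free text allowed).
#' @param diagnosis_probs named probabilities for CN/MCI/AD.
#' @param stage_sampling `"diagnosis"` draws each subject's stage from the
#'   diagnosis-specific distribution in the ground truth; `"uniform"` draws
#'   stages uniformly over 0..N and assigns the diagnosis from stage cut
#'   points (used for identifiability experiments needing even stage
#'   coverage).
#' @param cn_max_stage,mci_max_stage stage cut points for
#'   `stage_sampling = "uniform"`.
#' @param noise_sd z-score measurement noise SD (0 gives noise-free data).
#' @param csf_missing_prob probability a subject's CSF measurement is missing
#'   (1 emulates cohorts without CSF collection).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(cohort_label = "train",
                          diagnosis_probs = c(CN = 0.30, MCI = 0.45, AD = 0.25),
                          stage_sampling = c("diagnosis", "uniform"),
                          cn_max_stage = 5, mci_max_stage = 11,
                          noise_sd = 1,
                          csf_missing_prob = 0) {
  stage_sampling <- match.arg(stage_sampling)
  stopifnot(abs(sum(diagnosis_probs) - 1) < 1e-8, noise_sd >= 0,
            csf_missing_prob >= 0, csf_missing_prob <= 1)
  structure(list(cohort_label = cohort_label,
                 diagnosis_probs = diagnosis_probs,
                 stage_sampling = stage_sampling,
                 cn_max_stage = cn_max_stage, mci_max_stage = mci_max_stage,
                 noise_sd = noise_sd,
                 csf_missing_prob = csf_missing_prob),
            class = "cohort_config")
}

#' Generate a synthetic subject cohort
#'
#' Each subject receives a true subtype (multinomial with the ground-truth
#' fractions), a true stage, a noisy z-score vector on the subtype's
#' trajectory, raw regional volumes built by inverting the preprocessing
#' chain (control-scale volume, minus abnormality in control-SD units along
#' the panel direction, plus additive linear covariate confounds), an MMSE
#' declining linearly with stage, and a CSF amyloid value from a
#' two-component mixture whose abnormal-component weight increases with
#' stage. Hidden `true_*` columns record subtype, stage and the sampled
#' z-scores for oracle checks; they are what distinguishes a synthetic
#' cohort from a real one.
#'
#' @param gt a `sustain_truth`.
#' @param n_subjects number of subjects (0 gives an empty cohort).
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a `data.frame` of class `sustain_cohort`.
#' @export
generate_cohort <- function(gt, n_subjects, config = cohort_config(), seed = 1) {
  stopifnot(inherits(gt, "sustain_truth"), n_subjects >= 0)
  panel <- gt$panel
  B <- panel$n_biomarkers
  N <- panel$n_events
  n <- as.integer(n_subjects)

  if (n == 0L) {
    return(empty_cohort(panel))
  }

  with_local_seed(child_seed(seed, paste0("cohort-", config$cohort_label)), {
    subtype <- sample.int(gt$n_subtypes, n, replace = TRUE, prob = gt$fractions)

    if (config$stage_sampling == "diagnosis") {
      diagnosis <- sample(names(config$diagnosis_probs), n, replace = TRUE,
                          prob = config$diagnosis_probs)
      stage <- integer(n)
      for (dx in unique(diagnosis)) {
        idx <- diagnosis == dx
        stage[idx] <- sample(0:N, sum(idx), replace = TRUE,
                             prob = gt$stage_dist[[dx]])
      }
    } else {
      stage <- sample(0:N, n, replace = TRUE)
      diagnosis <- ifelse(stage <= config$cn_max_stage, "CN",
                   ifelse(stage <= config$mci_max_stage, "MCI", "AD"))
    }

    age <- pmin(95, pmax(55, stats::rnorm(n, 72, 7)))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    education <- round(pmin(22, pmax(6, stats::rnorm(n, 15, 3))))
    apoe_p <- c(CN = 0.28, MCI = 0.50, AD = 0.65)[diagnosis]
    apoe4 <- as.integer(stats::runif(n) < apoe_p)
    tiv <- stats::rnorm(n, 1.4e6, 1.3e5)

    # noisy z-scores on each subject's true trajectory
    Z <- matrix(0, n, B, dimnames = list(NULL, panel$names))
    for (s in unique(subtype)) {
      idx <- which(subtype == s)
      pos <- seq_positions(gt$sequences[[s]], B)
      E <- expected_matrix(pos, N)
      Z[idx, ] <- E[stage[idx] + 1L, , drop = FALSE]
    }
    Z <- Z + matrix(stats::rnorm(n * B, sd = config$noise_sd), n, B)

    # invert the preprocessing: control scale + confounds + abnormality
    covs <- cbind(age = age, sex = as.integer(sex == "M"),
                  education = education, apoe4 = apoe4, tiv = tiv)
    ref <- gt$covariate_reference
    centered <- sweep(covs, 2L, ref[colnames(covs)])
    confound <- centered %*% t(gt$covariate_effects)
    vol <- matrix(gt$control_mean, n, B, byrow = TRUE) + confound +
      sweep(Z, 2L, panel$sign * gt$control_sd, `*`)
    vol <- pmax(vol, 1) # physical floor; reached only in extreme noise draws
    colnames(vol) <- panel$names

    mmse <- round(pmin(30, pmax(0, 29 - gt$mmse_slope * stage +
                                  stats::rnorm(n, sd = gt$mmse_sd))))

    # CSF amyloid: abnormal-component probability rises with stage
    p_abn <- stats::plogis((stage - 6) / 3)
    abnormal <- stats::runif(n) < p_abn
    csf <- ifelse(abnormal,
                  stats::rnorm(n, gt$csf_params$positive["mean"],
                               gt$csf_params$positive["sd"]),
                  stats::rnorm(n, gt$csf_params$negative["mean"],
                               gt$csf_params$negative["sd"]))
    csf <- pmax(csf, 10)
    csf[stats::runif(n) < config$csf_missing_prob] <- NA_real_

    out <- data.frame(
      id = sprintf("%s_%05d", config$cohort_label, seq_len(n)),
      cohort = config$cohort_label,
      diagnosis = diagnosis,
      longitudinal = "none",
      vol,
      age = age, sex = sex, education = education, apoe4 = apoe4, tiv = tiv,
      mmse = mmse, csf_abeta = csf, visit_month = 0L,
      true_subtype = subtype, true_stage = stage,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    tz <- as.data.frame(Z)
    names(tz) <- paste0("true_z_", panel$names)
    out <- cbind(out, tz)
    class(out) <- c("sustain_cohort", "data.frame")
    attr(out, "panel_names") <- panel$names
    out
  })
}

empty_cohort <- function(panel) {
  cols <- c("id", "cohort", "diagnosis", "longitudinal", panel$names,
            "age", "sex", "education", "apoe4", "tiv", "mmse", "csf_abeta",
            "visit_month", "true_subtype", "true_stage",
            paste0("true_z_", panel$names))
  out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                              dimnames = list(NULL, cols)))
  class(out) <- c("sustain_cohort", "data.frame")
  attr(out, "panel_names") <- panel$names
  out
}

is_synthetic_cohort <- function(cohort) {
  all(c("true_subtype", "true_stage") %in% names(cohort))
}

#' Advance a synthetic cohort to a follow-up visit
#'
#' Each subject's true stage is incremented by a rounded draw from
#' Normal(drift_mean * months / 12, drift_sd * sqrt(months / 12)), the
#' longitudinal analogue of the observed mean 12-month progression of 0.8
#' stages (SD 1.5); the resulting stage is clamped to the model grid 0..N.
#' The true subtype never changes: subtype is a trait of the trajectory, and
#' any subtype switching measured downstream reflects assignment noise only.
#' Volumes, z-scores and MMSE are regenerated at the new stage with fresh
#' measurement noise; covariates and CSF are carried over.
#'
#' @param cohort a synthetic `sustain_cohort` (baseline visit).
#' @param months follow-up interval in months (>= 0).
#' @param gt the `sustain_truth` that generated the cohort.
#' @param seed integer seed.
#' @param noise_sd z-score noise SD at the follow-up visit.
#' @return a `sustain_cohort` of follow-up rows (same ids,
#'   `visit_month` advanced).
#' @export
advance_followup <- function(cohort, months, gt, seed = 1, noise_sd = 1) {
  stopifnot(inherits(gt, "sustain_truth"), months >= 0)
  if (!is_synthetic_cohort(cohort)) {
    stop("advance_followup requires a synthetic cohort (hidden true_* columns)")
  }
  panel <- gt$panel
  B <- panel$n_biomarkers
  N <- panel$n_events
  n <- nrow(cohort)
  if (n == 0L) return(cohort)

  with_local_seed(child_seed(seed, paste0("followup-", months)), {
    frac <- months / 12
    drift <- if (frac == 0) rep(0, n) else {
      round(stats::rnorm(n, gt$drift_mean * frac, gt$drift_sd * sqrt(frac)))
    }
    new_stage <- pmin(N, pmax(0L, cohort$true_stage + as.integer(drift)))

    Z <- matrix(0, n, B, dimnames = list(NULL, panel$names))
    for (s in unique(cohort$true_subtype)) {
      idx <- which(cohort$true_subtype == s)
      pos <- seq_positions(gt$sequences[[s]], B)
      E <- expected_matrix(pos, N)
      Z[idx, ] <- E[new_stage[idx] + 1L, , drop = FALSE]
    }
    Z <- Z + matrix(stats::rnorm(n * B, sd = noise_sd), n, B)

    covs <- cbind(age = cohort$age + frac, # subjects age with follow-up
                  sex = as.integer(cohort$sex == "M"),
                  education = cohort$education, apoe4 = cohort$apoe4,
                  tiv = cohort$tiv)
    ref <- gt$covariate_reference
    centered <- sweep(covs, 2L, ref[colnames(covs)])
    confound <- centered %*% t(gt$covariate_effects)
    vol <- pmax(matrix(gt$control_mean, n, B, byrow = TRUE) + confound +
                  sweep(Z, 2L, panel$sign * gt$control_sd, `*`), 1)

    out <- cohort
    out[panel$names] <- as.data.frame(vol)
    out$age <- covs[, "age"]
    out$mmse <- round(pmin(30, pmax(0, 29 - gt$mmse_slope * new_stage +
                                      stats::rnorm(n, sd = gt$mmse_sd))))
    out$visit_month <- cohort$visit_month + as.integer(months)
    out$true_stage <- new_stage
    out[paste0("true_z_", panel$names)] <- as.data.frame(Z)
    out
  })
}

#' Label stable vs progressive MCI from a follow-up visit
#'
#' Operational conversion rule for synthetic cohorts: an MCI subject is
#' labelled pMCI when the follow-up true stage reaches `threshold` and the
#' subject is either CSF amyloid-abnormal (below the ground-truth cut-off)
#' or, with probability `p_nonamyloid`, converts without amyloid evidence;
#' all other MCI subjects are sMCI. Non-MCI subjects keep the label "none".
#'
#' @param baseline,followup matched synthetic cohorts (same ids).
#' @param gt the generating `sustain_truth`.
#' @param threshold conversion stage threshold.
#' @param p_nonamyloid probability of conversion without amyloid abnormality.
#' @param seed integer seed.
#' @return `baseline` with the `longitudinal` column filled in.
#' @export
label_conversions <- function(baseline, followup, gt, threshold = 12,
                              p_nonamyloid = 0.2, seed = 1) {
  stopifnot(identical(baseline$id, followup$id))
  with_local_seed(child_seed(seed, "conversion-labels"), {
    mci <- baseline$diagnosis == "MCI"
    crossed <- followup$true_stage >= threshold
    abn <- !is.na(baseline$csf_abeta) &
      baseline$csf_abeta < gt$csf_params$cutoff
    lucky <- stats::runif(nrow(baseline)) < p_nonamyloid
    pmci <- mci & crossed & (abn | lucky)
    baseline$longitudinal <- ifelse(!mci, "none", ifelse(pmci, "pMCI", "sMCI"))
    baseline
  })
}
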