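#' Heuristic atrophy subtype from visual ratings
#'
#' Classifies pre-thresholded visual ratings (medial temporal atrophy MTA,
#' posterior atrophy PA, frontal global cortical atrophy GCA-F) into the four
#' heuristic atrophy subtypes: typical (abnormal MTA with abnormal PA and/or
#' GCA-F), hippocampal-sparing (abnormal PA and/or GCA-F with normal MTA),
#' limbic-predominant (abnormal MTA alone) and minimal (all normal). Every
#' rating triple maps to exactly one category.
#'
#' @param mta_abnormal,pa_abnormal,gcaf_abnormal logical vectors.
#' @return factor with levels typical, hippocampal-sparing,
#'   limbic-predominant, minimal.
#' @export
visual_rating_subtype <- function(mta_abnormal, pa_abnormal, gcaf_abnormal) {
  stopifnot(is.logical(mta_abnormal), is.logical(pa_abnormal),
            is.logical(gcaf_abnormal),
            !anyNA(mta_abnormal), !anyNA(pa_abnormal), !anyNA(gcaf_abnormal))
  post <- pa_abnormal | gcaf_abnormal
  out <- ifelse(mta_abnormal & post, "typical",
         ifelse(!mta_abnormal & post, "hippocampal-sparing",
         ifelse(mta_abnormal, "limbic-predominant", "minimal")))
  factor(out, levels = c("typical", "hippocampal-sparing",
                         "limbic-predominant", "minimal"))
}

#' Longitudinal subtype consistency
#'
#' Fraction of subjects keeping the same subtype between two assignment
#' visits, plus the full subtype-transition table. Subjects with an
#' undefined subtype (stage 0 or N) at either visit are excluded, matching
#' the exclusion of those stages from subtyping.
#'
#' @param a0,a1 assignment data.frames from [assign_subjects()] with row
#'   names as subject ids (or `id` columns).
#' @return list with `stable_fraction`, `n_compared` and `transitions`.
#' @export
subtype_consistency <- function(a0, a1) {
  id0 <- if ("id" %in% names(a0)) a0$id else rownames(a0)
  id1 <- if ("id" %in% names(a1)) a1$id else rownames(a1)
  common <- intersect(id0, id1)
  if (length(common) == 0L) stop("no overlapping subject ids between visits")
  s0 <- a0$subtype[match(common, id0)]
  s1 <- a1$subtype[match(common, id1)]
  keep <- !is.na(s0) & !is.na(s1)
  s0 <- s0[keep]; s1 <- s1[keep]
  if (length(s0) == 0L) stop("no subjects with defined subtype at both visits")
  lev <- sort(unique(c(s0, s1)))
  transitions <- table(baseline = factor(s0, levels = lev),
                       followup = factor(s1, levels = lev))
  list(stable_fraction = mean(s0 == s1),
       n_compared = length(s0),
       transitions = transitions)
}

#' Linear regression of cognition on model stage
#'
#' Regresses MMSE on assigned stage by ordinary least squares. By default the
#' regression runs on per-stage mean MMSE (one point per observed stage),
#' summarising the cohort-level cognitive trajectory; `subject_level = TRUE`
#' switches to raw subject points. With `per_subtype = TRUE` a separate fit
#' is returned per assigned subtype.
#'
#' @param assignments data.frame with `stage` (and `subtype`) columns.
#' @param mmse numeric MMSE values aligned with `assignments`.
#' @param per_subtype fit separately per subtype.
#' @param subject_level regress raw subject points instead of per-stage
#'   means.
#' @return data.frame with slope, intercept, r.squared, n_stages (and
#'   subtype when `per_subtype`), plus a `"mode"` attribute recording the
#'   aggregation choice.
#' @export
stage_cognition_fit <- function(assignments, mmse, per_subtype = FALSE,
                                subject_level = FALSE) {
  fit_one <- function(stage, mm) {
    keep <- !is.na(stage) & !is.na(mm)
    stage <- stage[keep]; mm <- mm[keep]
    if (length(unique(stage)) < 3L) stop("need data at >= 3 distinct stages")
    if (!subject_level) {
      mm <- tapply(mm, stage, mean)
      stage <- as.numeric(names(mm))
      mm <- as.numeric(mm)
    }
    fit <- stats::lm(mm ~ stage)
    tss <- sum((mm - mean(mm))^2)
    r2 <- if (tss < 1e-12) 0 else 1 - sum(stats::residuals(fit)^2) / tss
    data.frame(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r.squared = r2,
               n_stages = length(unique(stage)))
  }
  out <- if (per_subtype) {
    keep <- !is.na(assignments$subtype)
    res <- lapply(split(seq_len(nrow(assignments))[keep],
                        assignments$subtype[keep]),
                  function(idx) fit_one(assignments$stage[idx], mmse[idx]))
    cbind(subtype = as.integer(names(res)), do.call(rbind, res))
  } else {
    fit_one(assignments$stage, mmse)
  }
  attr(out, "mode") <- if (subject_level) "subject-level" else "per-stage means"
  rownames(out) <- NULL
  out
}

#' Build the conversion-classifier feature table
#'
#' Assembles the predictors for stable vs progressive MCI classification from
#' any subset of subtype (reference-coded indicator columns), stage, MMSE and
#' CSF amyloid. Rows missing any required feature are excluded and counted;
#' subjects with undefined subtype are only excluded when subtype is among
#' the requested features.
#'
#' @param assignments assignment data.frame (`subtype`, `stage`).
#' @param mmse,abeta numeric vectors aligned with `assignments` (NA allowed).
#' @param features character subset of `c("subtype", "stage", "mmse",
#'   "abeta")`.
#' @param n_subtypes total subtype count C (for indicator coding).
#' @return numeric feature matrix with a `"kept"` logical attribute and an
#'   `"n_excluded"` count.
#' @export
conversion_features <- function(assignments, mmse = NULL, abeta = NULL,
                                features, n_subtypes = NULL) {
  if (length(features) == 0L) stop("empty feature specification")
  features <- match.arg(features, c("subtype", "stage", "mmse", "abeta"),
                        several.ok = TRUE)
  n <- nrow(assignments)
  cols <- list()
  kept <- rep(TRUE, n)
  if ("subtype" %in% features) {
    if (is.null(n_subtypes)) n_subtypes <- max(assignments$subtype, na.rm = TRUE)
    kept <- kept & !is.na(assignments$subtype)
    if (n_subtypes > 1L) {
      for (cc in 2:n_subtypes) {
        cols[[paste0("subtype", cc)]] <- as.numeric(assignments$subtype == cc)
      }
    }
  }
  if ("stage" %in% features) cols[["stage"]] <- as.numeric(assignments$stage)
  if ("mmse" %in% features) {
    stopifnot(!is.null(mmse))
    kept <- kept & !is.na(mmse)
    cols[["mmse"]] <- as.numeric(mmse)
  }
  if ("abeta" %in% features) {
    stopifnot(!is.null(abeta))
    kept <- kept & !is.na(abeta)
    cols[["abeta"]] <- as.numeric(abeta)
  }
  X <- do.call(cbind, cols)
  X <- X[kept, , drop = FALSE]
  structure(X, kept = kept, n_excluded = sum(!kept))
}

#' Fit the stable/progressive MCI logistic classifier
#'
#' Maximum-likelihood multivariate logistic regression (iteratively
#' reweighted least squares via `stats::glm`) of conversion labels on the
#' feature table. Perfect separation is detected and flagged rather than
#' failing.
#'
#' @param features numeric feature matrix from [conversion_features()].
#' @param labels factor/character/integer with two classes; `"pMCI"` (or the
#'   larger level) is the positive class.
#' @return object of class `conversion_model` with coefficients, the glm fit,
#'   and `converged`/`separation` flags.
#' @export
fit_conversion_classifier <- function(features, labels) {
  y <- conversion_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(nrow(features) == length(y))
  df <- data.frame(.y = y, features, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(coefficients = stats::coef(fit), fit = fit,
                 converged = fit$converged, separation = separation,
                 feature_names = colnames(features)),
            class = "conversion_model")
}

conversion_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  lab <- as.character(labels)
  pos <- if ("pMCI" %in% lab) "pMCI" else sort(unique(lab))[2L]
  as.integer(lab == pos)
}

#' Predicted conversion scores
#'
#' @param object a `conversion_model`.
#' @param features feature matrix with the model's columns.
#' @param ... unused.
#' @return predicted conversion probabilities.
#' @export
predict.conversion_model <- function(object, features, ...) {
  stats::predict(object$fit, newdata = as.data.frame(features), type = "response")
}

#' Receiver-operating characteristic curve
#'
#' Threshold sweep over the unique scores; the AUC is the trapezoidal area,
#' which with half-credit for tied scores equals the rank-sum (concordance)
#' probability estimator P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels two-class labels; positive class as in
#'   [fit_conversion_classifier()].
#' @return object of class `roc_curve` with `fpr`, `tpr`, `auc`, and the
#'   retained scores/labels for variance estimation.
#' @export
roc_curve <- function(scores, labels) {
  y <- conversion_labels(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 scores = scores, labels = y),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half credit); for each negative, the fraction of positives it
# loses to. Their means both equal the rank-sum AUC.
delong_placements <- function(roc) {
  xs <- roc$scores[roc$labels == 1L]
  ys <- roc$scores[roc$labels == 0L]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong comparison of two ROC curves
#'
#' Nonparametric test of the AUC difference using placement-value variance
#' estimates. The unpaired variant (default; appropriate when the two curves
#' come from disjoint cohorts such as a training and a test set) sums the two
#' independent AUC variances; the paired variant subtracts twice the
#' placement covariance computed over matched subjects.
#'
#' @param roc_a,roc_b `roc_curve` objects carrying scores and labels.
#' @param paired the two curves were computed on the same subjects in the
#'   same order.
#' @return list with `auc_a`, `auc_b`, `auc_diff`, `z` and two-sided
#'   `p.value`.
#' @export
delong_compare <- function(roc_a, roc_b, paired = FALSE) {
  pa <- delong_placements(roc_a)
  pb <- delong_placements(roc_b)
  var_auc <- function(p) {
    stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
  }
  v <- var_auc(pa) + var_auc(pb)
  if (paired) {
    if (length(pa$v10) != length(pb$v10) || length(pa$v01) != length(pb$v01)) {
      stop("paired comparison requires matched subjects in the same order")
    }
    v <- v - 2 * (stats::cov(pa$v10, pb$v10) / length(pa$v10) +
                  stats::cov(pa$v01, pb$v01) / length(pa$v01))
  }
  d <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = 0, z = 0,
                  p.value = 1))
    }
    stop("degenerate DeLong variance")
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = d, z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Group difference tests
#'
#' One-way ANOVA for a continuous outcome across groups, or a Pearson
#' chi-square test (without continuity correction) for a contingency table of
#' counts; two-sided p-values at the conventional alpha of 0.05.
#'
#' @param values numeric outcome vector, or a contingency table/matrix of
#'   counts (in which case `groups` is ignored).
#' @param groups group labels aligned with `values`.
#' @return list with `method`, `statistic`, `df` and `p.value`.
#' @export
group_difference_tests <- function(values, groups = NULL) {
  if (is.matrix(values) || is.table(values)) {
    tst <- stats::chisq.test(values, correct = FALSE)
    return(list(method = "chi-square",
                statistic = unname(tst$statistic),
                df = unname(tst$parameter), p.value = tst$p.value))
  }
  stopifnot(!is.null(groups), length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) == 0L)) stop("empty group")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1L]]
  list(method = "anova",
       statistic = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]),
       p.value = s[["Pr(>F)"]][1L])
}
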