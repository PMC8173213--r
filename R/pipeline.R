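#' Pipeline run configuration
#'
#' Bundles every tunable of the train-on-one-cohort / validate-on-another
#' workflow. All randomness downstream derives from `seed`; every option is
#' echoed verbatim (with a content hash) into the outputs.
#'
#' @param seed master integer seed.
#' @param panel a `sustain_panel`.
#' @param cutoff amyloid-negative CSF cut-off (pg/ml).
#' @param fit_adjustment_on `"all"` or `"controls"` (covariate regression
#'   fitting subset).
#' @param max_subtypes cap on the subtype count (must be <= 5).
#' @param folds CVIC folds; set `use_cvic = FALSE` to fit `max_subtypes`
#'   directly.
#' @param use_cvic select the subtype count by cross-validation.
#' @param fit a [fit_config()].
#' @param feature_sets list of predictor subsets for the conversion
#'   classifier.
#' @param output_dir optional directory for artifacts (model JSON,
#'   assignment CSVs, report JSON, log). NULL returns results in memory only.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1, panel = default_panel(), cutoff = 192,
                       fit_adjustment_on = "all", max_subtypes = 3,
                       folds = 10, use_cvic = FALSE, fit = fit_config(),
                       feature_sets = list(
                         c("subtype", "stage"),
                         c("mmse", "abeta"),
                         c("subtype", "stage", "mmse", "abeta")
                       ),
                       output_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (max_subtypes > 5) stop("the maximum number of subtypes is 5")
  structure(list(seed = as.integer(seed), panel = panel, cutoff = cutoff,
                 fit_adjustment_on = fit_adjustment_on,
                 max_subtypes = max_subtypes, folds = folds,
                 use_cvic = use_cvic, fit = fit, feature_sets = feature_sets,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full training/validation pipeline
#'
#' Orchestrates preprocessing (covariate adjustment per cohort, z-scoring
#' against the training cohort's amyloid-negative CN reference, CSF
#' rescaling), model fitting (optionally CVIC subtype-count selection),
#' subject assignment for both cohorts, and the validation battery
#' (longitudinal subtype consistency when follow-up visits are supplied,
#' stage-cognition regression, conversion classification with ROC curves and
#' unpaired DeLong train-vs-test comparisons). Rerunning with the same
#' config and inputs reproduces every numeric output bit-identically.
#'
#' @param config a [run_config()].
#' @param train training cohort (table or CSV path).
#' @param test optional test cohort; when absent the report is training-only
#'   with validation sections marked absent.
#' @param train_followup,test_followup optional follow-up visits for the
#'   subtype-consistency check.
#' @return a report list (also written as JSON when `config$output_dir` is
#'   set).
#' @export
run_pipeline <- function(config, train, test = NULL,
                         train_followup = NULL, test_followup = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$max_subtypes > 5) stop("the maximum number of subtypes is 5")
  panel <- config$panel
  load_cohort <- function(x) {
    if (is.character(x)) read_cohort(x, panel) else x
  }
  train <- load_cohort(train)
  test <- load_cohort(test)
  train_followup <- load_cohort(train_followup)
  test_followup <- load_cohort(test_followup)

  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("sustainr"))))
  stage_name <- "preprocess"
  report <- tryCatch({
    prep <- preprocess_cohorts(train, test, panel, config$cutoff,
                               config$fit_adjustment_on)

    stage_name <- "fit"
    cvic <- NULL
    n_subtypes <- config$max_subtypes
    if (config$use_cvic) {
      cvic <- cvic_select(prep$z_train, config$max_subtypes, config$folds,
                          panel, config$fit, seed = child_seed(config$seed, "cvic"),
                          diagnosis = train$diagnosis)
      n_subtypes <- cvic$selected
    }
    model <- fit_sustain(prep$z_train, n_subtypes, panel, config$fit,
                         seed = child_seed(config$seed, "fit"))

    stage_name <- "assign"
    a_train <- assign_subjects(model, prep$z_train,
                               config$fit$weight_fractions)
    a_train <- cbind(id = train$id, a_train)
    a_test <- NULL
    if (!is.null(test)) {
      a_test <- assign_subjects(model, prep$z_test,
                                config$fit$weight_fractions)
      a_test <- cbind(id = test$id, a_test)
    }

    stage_name <- "validate"
    validation <- validate_cohorts(config, model, prep,
                                   train, test, a_train, a_test,
                                   train_followup, test_followup)

    list(config_hash = config_hash(config),
         seed = config$seed,
         n_subtypes = model$n_subtypes,
         cvic = if (is.null(cvic)) NULL else
           list(scores = unname(cvic$cvic), selected = cvic$selected),
         fractions = model$fractions,
         train_loglik = attr(model, "loglik"),
         model = model,
         assignments_train = a_train,
         assignments_test = a_test,
         validation = validation)
  }, error = function(e) {
    stop("pipeline stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    echo_cfg <- strip_env(config)
    echo_cfg$output_dir <- NULL # location, not configuration
    write_model(report$model, out("model.json"), config = echo_cfg)
    utils::write.csv(report$assignments_train, out("assignments_train.csv"),
                     row.names = FALSE)
    if (!is.null(report$assignments_test)) {
      utils::write.csv(report$assignments_test, out("assignments_test.csv"),
                       row.names = FALSE)
    }
    json_report <- report[setdiff(names(report),
                                  c("model", "assignments_train",
                                    "assignments_test"))]
    writeLines(jsonlite::toJSON(clean_for_json(json_report), auto_unbox = TRUE,
                                digits = NA, null = "null"),
               out("report.json"))
    writeLines(log_lines, out("run.log"))
  }
  invisible(report)
}

validate_cohorts <- function(config, model, prep, train, test,
                             a_train, a_test, train_followup, test_followup) {
  val <- list()

  consistency_for <- function(baseline_assign, followup, cohort_label) {
    if (is.null(followup)) return(NULL)
    model_f <- fit_covariate_adjustment(followup, config$panel,
                                        subset = NULL)
    adj <- apply_adjustment(model_f, followup)
    zf <- compute_zscores(adj, prep$stats, config$panel)
    af <- assign_subjects(model, zf, config$fit$weight_fractions)
    af <- cbind(id = followup$id, af)
    cons <- subtype_consistency(baseline_assign, af)
    list(stable_fraction = cons$stable_fraction,
         n_compared = cons$n_compared,
         transitions = as.matrix(unclass(cons$transitions)))
  }
  val$consistency_train <- consistency_for(a_train, train_followup, "train")
  val$consistency_test <- if (!is.null(test)) {
    consistency_for(a_test, test_followup, "test")
  } else NULL

  cognition_for <- function(assign, cohort) {
    if (is.null(cohort)) return(NULL)
    overall <- tryCatch(stage_cognition_fit(assign, cohort$mmse),
                        error = function(e) NULL)
    per_sub <- tryCatch(stage_cognition_fit(assign, cohort$mmse,
                                            per_subtype = TRUE),
                        error = function(e) NULL)
    list(overall = overall, per_subtype = per_sub,
         mode = "per-stage means")
  }
  val$cognition_train <- cognition_for(a_train, train)
  val$cognition_test <- cognition_for(a_test, test)

  # conversion classification: train the logistic model on training-set MCI,
  # score both cohorts, compare ROC curves across cohorts (unpaired DeLong)
  val$conversion <- lapply(config$feature_sets, function(fs) {
    res <- tryCatch(
      conversion_analysis(model, fs, train, a_train, test, a_test,
                          prep),
      error = function(e) list(features = paste(fs, collapse = "+"),
                               status = paste("absent:", conditionMessage(e)))
    )
    res
  })
  val
}

conversion_analysis <- function(model, fs, train, a_train, test, a_test,
                                prep) {
  mci_rows <- function(cohort) {
    !is.null(cohort) & cohort$longitudinal %in% c("sMCI", "pMCI")
  }
  tr <- which(mci_rows(train))
  if (length(tr) == 0L) stop("no labelled MCI subjects in training cohort")
  feats_tr <- conversion_features(a_train[tr, ], mmse = train$mmse[tr],
                                  abeta = train$csf_abeta[tr],
                                  features = fs,
                                  n_subtypes = model$n_subtypes)
  kept_tr <- attr(feats_tr, "kept")
  labs_tr <- train$longitudinal[tr][kept_tr]
  clf <- fit_conversion_classifier(feats_tr, labs_tr)
  roc_tr <- roc_curve(predict(clf, feats_tr), labs_tr)

  out <- list(features = paste(fs, collapse = "+"),
              status = "ok",
              coefficients = as.list(clf$coefficients),
              separation = clf$separation,
              auc_train = roc_tr$auc,
              n_train = length(labs_tr))
  if (!is.null(test)) {
    te <- which(mci_rows(test))
    abeta_te <- if (!is.null(prep$test_csf_rescaled)) {
      prep$test_csf_rescaled[te]
    } else test$csf_abeta[te]
    if ("abeta" %in% fs && all(is.na(abeta_te))) {
      out$status <- "absent: test-cohort CSF missing by design"
      return(out)
    }
    feats_te <- conversion_features(a_test[te, ], mmse = test$mmse[te],
                                    abeta = abeta_te, features = fs,
                                    n_subtypes = model$n_subtypes)
    kept_te <- attr(feats_te, "kept")
    labs_te <- test$longitudinal[te][kept_te]
    roc_te <- roc_curve(predict(clf, feats_te), labs_te)
    dl <- delong_compare(roc_tr, roc_te, paired = FALSE)
    out$auc_test <- roc_te$auc
    out$n_test <- length(labs_te)
    out$delong_p <- dl$p.value
  }
  out
}

# drop environments/functions so config echoes serialize cleanly
strip_env <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_env)
    return(x)
  }
  if (is.function(x) || is.environment(x)) return(NULL)
  x
}

clean_for_json <- function(x) {
  if (inherits(x, "sustain_panel")) {
    return(list(names = x$names, direction = x$direction))
  }
  if (is.list(x)) return(lapply(x, clean_for_json))
  x
}
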