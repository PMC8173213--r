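#' Read a cohort CSV
#'
#' Expects the documented header: `id, cohort, diagnosis, longitudinal`, one
#' column per panel region (raw volumes in mm^3), `age, sex, education,
#' apoe4, tiv, mmse, csf_abeta, visit_month`, plus optional hidden `true_*`
#' columns for synthetic cohorts. Missing mandatory columns and non-numeric
#' volume columns are hard errors; row-level violations (non-positive
#' volumes, MMSE outside 0..30, negative visit month) are collected in the
#' `"row_errors"` attribute and the offending rows dropped, never silently.
#'
#' @param path CSV file path.
#' @param panel a `sustain_panel`.
#' @return a `sustain_cohort` data.frame.
#' @export
read_cohort <- function(path, panel = default_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("id", "cohort", "diagnosis", panel$names, "age", "sex",
                 "education", "apoe4", "tiv", "mmse", "csf_abeta",
                 "visit_month")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (v in panel$names) {
    if (!is.numeric(df[[v]])) stop("non-numeric volume column: ", v)
  }
  if (!"longitudinal" %in% names(df)) df$longitudinal <- "none"

  reasons <- character(nrow(df))
  bad_vol <- rowSums(as.matrix(df[, panel$names, drop = FALSE]) <= 0,
                     na.rm = TRUE) > 0
  reasons[bad_vol] <- "non-positive volume"
  bad_mmse <- !is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30)
  reasons[bad_mmse & reasons == ""] <- "mmse outside 0..30"
  bad_visit <- !is.na(df$visit_month) & df$visit_month < 0
  reasons[bad_visit & reasons == ""] <- "negative visit_month"

  bad <- reasons != ""
  row_errors <- data.frame(id = df$id[bad], reason = reasons[bad],
                           stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sustain_cohort", "data.frame")
  attr(out, "panel_names") <- panel$names
  attr(out, "row_errors") <- row_errors
  out
}

#' Write a cohort CSV
#'
#' @param cohort a cohort table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Sequences are written as ordered (region, level) pairs along with the
#' mixture fractions, noise SDs, panel definition and an echo of the
#' configuration used to fit.
#'
#' @param model a `sustain_model`.
#' @param path output path.
#' @param config optional configuration to echo.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, config = NULL) {
  obj <- list(
    panel = list(names = model$panel$names, direction = model$panel$direction),
    n_subtypes = model$n_subtypes,
    n_stages = model$n_stages,
    fractions = model$fractions,
    sigma = model$sigma,
    sequences = lapply(model$sequences, function(s) {
      data.frame(region = model$panel$names[event_biomarker(s)],
                 level = event_level(s))
    }),
    loglik = attr(model, "loglik")
  )
  if (!is.null(config)) {
    obj$config <- config
    obj$config_hash <- config_hash(config)
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return a `sustain_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  panel <- biomarker_panel(obj$panel$names, obj$panel$direction)
  seqs <- lapply(obj$sequences, function(df) {
    event_sequence(match(df$region, panel$names), df$level, panel$n_biomarkers)
  })
  m <- sustain_model(seqs, obj$fractions, panel, obj$sigma)
  if (!is.null(obj$loglik)) attr(m, "loglik") <- obj$loglik
  m
}

# Stable content hash over the deparsed configuration; embedded in every
# output artifact so results can be traced to their configuration. The
# output directory is a location, not a setting, and is excluded so reruns
# into different directories hash identically.
config_hash <- function(config) {
  config$output_dir <- NULL
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  h <- 16777619
  for (b in utf8ToInt(txt)) {
    h <- (h * 257 + b) %% 2147483629
  }
  sprintf("%08x", h)
}
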