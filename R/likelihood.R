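#' @name model-likelihood
#' @title Likelihood of z-scores under a z-score event progression model
#'
#' @description
#' Under a subtype's event sequence, a subject at stage k has expected
#' z-scores given by the piecewise-linear trajectory of every biomarker, and
#' observed z-scores are modelled as independent Gaussians around those
#' expectations with per-biomarker SD sigma. The stage is latent with a
#' uniform prior over the grid 0..N; subtypes mix with fractions f_c.
NULL

log_row_sum_exp <- function(L) {
  mx <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  mx + log(rowSums(exp(L - mx)))
}

# n x (N + 1) matrix of per-stage Gaussian log-likelihoods via the quadratic
# expansion sum_b ((z - E)/sigma)^2 = |z/sigma|^2 - 2 (z/sigma^2)'E + |E/sigma|^2,
# so the stage sweep is a single matrix product (hot path of all fitting).
stage_loglik_matrix <- function(Z, E, sigma) {
  B <- ncol(Z)
  if (length(sigma) == 1L) sigma <- rep(sigma, B)
  Zs <- sweep(Z, 2L, sigma^2, `/`)
  A <- rowSums(Z * Zs)                       # |z/sigma|^2 per subject
  Es <- sweep(E, 2L, sigma, `/`)
  C <- rowSums(Es * Es)                      # |E/sigma|^2 per stage
  X <- tcrossprod(Zs, E)                     # n x (N+1)
  cst <- sum(log(sigma)) + B * 0.5 * log(2 * pi)
  -0.5 * (outer(A, C, `+`) - 2 * X) - cst
}

seq_expected <- function(events, n_biomarkers) {
  expected_matrix(seq_positions(events, n_biomarkers), length(events))
}

#' Stage likelihoods of one z-score vector under one sequence
#'
#' Computes, for every stage k on the grid 0..N, the likelihood of the
#' z-vector under the sequence's trajectory, the normalized stage posterior
#' (uniform stage prior), and the log marginal likelihood (uniform-prior
#' average over stages).
#'
#' @param z numeric z-vector of length B.
#' @param events event sequence.
#' @param sigma per-biomarker noise SD (scalar or length-B vector, > 0).
#' @return list with `loglik` (length N + 1), `posterior` (sums to 1) and
#'   `log_marginal`.
#' @export
stage_likelihoods <- function(z, events, sigma = 1) {
  stopifnot(all(sigma > 0))
  B <- length(z)
  stopifnot(length(events) == 3L * B)
  E <- seq_expected(events, B)
  L <- stage_loglik_matrix(matrix(z, nrow = 1L), E, sigma)[1L, ]
  m <- max(L)
  w <- exp(L - m)
  list(loglik = L,
       posterior = w / sum(w),
       log_marginal = m + log(sum(w)) - log(length(L)))
}

# Per-subject log marginal likelihood under one sequence (vectorized).
seq_log_marginals <- function(Z, events, sigma) {
  E <- seq_expected(events, ncol(Z))
  L <- stage_loglik_matrix(Z, E, sigma)
  log_row_sum_exp(L) - log(ncol(L))
}

#' Construct a fitted progression model object
#'
#' @param sequences list of event sequences, one per subtype.
#' @param fractions mixture fractions (sum to 1, each >= 0).
#' @param panel a `sustain_panel`.
#' @param sigma per-biomarker noise SD (scalar or length-B), default 1
#'   (control-referenced z-scores).
#' @return an object of class `sustain_model`.
#' @export
sustain_model <- function(sequences, fractions, panel, sigma = 1) {
  C <- length(sequences)
  if (C > 5L) stop("the maximum number of subtypes is 5")
  stopifnot(length(fractions) == C, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, all(sigma > 0))
  for (s in sequences) validate_sequence(s, panel$n_biomarkers)
  structure(
    list(sequences = sequences, fractions = as.numeric(fractions),
         panel = panel,
         sigma = if (length(sigma) == 1L) rep(sigma, panel$n_biomarkers) else sigma,
         n_subtypes = C, n_stages = panel$n_events),
    class = "sustain_model"
  )
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("Z-score progression model:", x$n_subtypes, "subtype(s),",
      x$n_stages, "stages,", x$panel$n_biomarkers, "biomarkers\n")
  cat("  fractions:", paste(sprintf("%.3f", x$fractions), collapse = " "), "\n")
  invisible(x)
}

#' Total data log-likelihood of a z-score matrix under a model
#'
#' Sum over subjects of the log of the subtype mixture of stage-marginal
#' likelihoods: `log sum_c f_c * mean_k P(z | S_c, k)`.
#'
#' @param Z z-score matrix (subjects x biomarkers).
#' @param model a `sustain_model`.
#' @return scalar log-likelihood.
#' @export
data_log_likelihood <- function(Z, model) {
  Z <- as.matrix(Z)
  if (nrow(Z) == 0L) stop("empty data")
  LM <- subtype_log_marginals(Z, model)
  sum(log_row_sum_exp(sweep(LM, 2L, log(model$fractions), `+`)))
}

# n x C matrix of per-subject log marginals under each subtype sequence.
subtype_log_marginals <- function(Z, model) {
  matrix(unlist(lapply(model$sequences,
                       function(s) seq_log_marginals(Z, s, model$sigma))),
         nrow = nrow(Z), ncol = model$n_subtypes)
}
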