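#' Derive a child seed from a parent seed and a label
#'
#' All randomness in the package flows from one explicit integer seed.
#' Independent random streams (subtype draws, covariates, noise, folds,
#' optimizer restarts, ...) are obtained by hashing the parent seed together
#' with a stream label, so that adding a consumer never perturbs the draws of
#' another.
#'
#' @param seed parent integer seed.
#' @param label character stream label.
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # FNV-1a style mixing over the label bytes, folded with the parent seed.
  h <- (seed %% 2147483647) + 1
  for (b in utf8ToInt(label)) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so no package function mutates global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}
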