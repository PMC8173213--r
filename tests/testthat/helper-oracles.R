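# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package's vectorized implementations.

# expected z-score by direct interpolation through the event positions
oracle_expected_z <- function(events, stage, biomarker, B) {
  p <- sapply(1:3, function(l) which(events == (biomarker - 1L) * 3L + l))
  xs <- c(0, p[1], p[2], p[3])
  ys <- c(0, 1, 2, 3)
  if (stage >= p[3]) return(3)
  for (seg in 1:3) {
    if (stage <= xs[seg + 1]) {
      return(ys[seg] + (ys[seg + 1] - ys[seg]) *
               (stage - xs[seg]) / (xs[seg + 1] - xs[seg]))
    }
  }
  stop("unreachable")
}

# per-stage likelihood vector and uniform-prior marginal via double loop
oracle_stage_likelihood <- function(z, events, sigma) {
  B <- length(z)
  N <- length(events)
  sig <- if (length(sigma) == 1) rep(sigma, B) else sigma
  lik <- numeric(N + 1)
  for (k in 0:N) {
    p <- 1
    for (b in 1:B) {
      mu <- oracle_expected_z(events, k, b, B)
      p <- p * dnorm(z[b], mean = mu, sd = sig[b])
    }
    lik[k + 1] <- p
  }
  list(lik = lik, marginal = mean(lik))
}

# total mixture log-likelihood via triple loop (subjects x subtypes x stages)
oracle_data_loglik <- function(Z, sequences, fractions, sigma) {
  total <- 0
  for (i in seq_len(nrow(Z))) {
    mix <- 0
    for (cc in seq_along(sequences)) {
      res <- oracle_stage_likelihood(Z[i, ], sequences[[cc]], sigma)
      mix <- mix + fractions[cc] * res$marginal
    }
    total <- total + log(mix)
  }
  total
}

# small helpers shared across test files -------------------------------------

toy_panel <- function() biomarker_panel(c("A", "B"), "atrophy")

# the interleaved 6-event toy sequence A1 B1 A2 B2 A3 B3
toy_sequence <- function() event_sequence(c(1, 2, 1, 2, 1, 2),
                                          c(1, 1, 2, 2, 3, 3), 2)

# z-score matrix of noise-free subjects spread over stages of a sequence
noisefree_z <- function(events, stages, B) {
  t(vapply(stages, function(k) {
    vapply(seq_len(B), function(b) oracle_expected_z(events, k, b, B),
           numeric(1))
  }, numeric(B)))
}

quick_fit_config <- function(...) {
  defaults <- list(restarts = 3, split_tries = 1, split_restarts = 2,
                   em_max_iter = 10, em_candidate_iter = 3)
  do.call(fit_config, utils::modifyList(defaults, list(...)))
}
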