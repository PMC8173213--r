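#' Fitting configuration
#'
#' Controls the sequence optimizer and the mixture refinement. The point
#' estimate comes from multi-start greedy hill climbing (best-improvement
#' relocation of single events); subtype models are initialized
#' hierarchically by splitting the clusters of the (C-1)-subtype model and
#' refined by alternating responsibility updates and responsibility-weighted
#' sequence optimization.
#'
#' @param restarts random restarts for a full single-sequence fit.
#' @param split_tries random bipartitions tried per cluster when adding a
#'   subtype.
#' @param split_restarts restarts for the half-cluster fits during
#'   initialization.
#' @param max_passes cap on hill-climbing passes (Inf = run to a local
#'   optimum).
#' @param em_max_iter cap on alternation iterations.
#' @param em_tol stop when the log-likelihood improves by less than this.
#' @param em_passes cap on hill-climbing passes inside each alternation
#'   M-step (the sequence starts from its previous optimum, so few passes
#'   are needed).
#' @param em_candidate_iter alternation iterations used to screen split
#'   candidates before the winner is refined with `em_max_iter`.
#' @param refine_cycles hard-assignment refit cycles after each subtype-count
#'   refinement: subjects are hard-assigned, each subtype's sequence is
#'   refitted from scratch on its members, and the alternation rerun; the
#'   result is kept only when it improves the log-likelihood. Escapes the
#'   local optima that responsibility-weighted single-event moves cannot.
#' @param n_finalists split candidates fully refined per subtype-count
#'   growth step: near-tied candidates can finish in very different basins,
#'   so refining only the screening winner leaves likelihood on the table.
#' @param sigma per-biomarker noise SD (scalar or vector); 1 by default since
#'   inputs are control-referenced z-scores.
#' @param weight_fractions use mixture fractions when assigning subjects.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(restarts = 25, split_tries = 2, split_restarts = 3,
                       max_passes = Inf, em_max_iter = 30, em_tol = 1e-4,
                       em_passes = 4, em_candidate_iter = 4,
                       refine_cycles = 2, n_finalists = 3,
                       sigma = 1, weight_fractions = TRUE) {
  stopifnot(restarts >= 1, split_tries >= 1, split_restarts >= 1,
            em_max_iter >= 1, em_tol > 0, em_passes >= 1,
            em_candidate_iter >= 1, refine_cycles >= 0, n_finalists >= 1,
            all(sigma > 0))
  structure(list(restarts = restarts, split_tries = split_tries,
                 split_restarts = split_restarts, max_passes = max_passes,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 em_passes = em_passes, em_candidate_iter = em_candidate_iter,
                 refine_cycles = refine_cycles, n_finalists = n_finalists,
                 sigma = sigma, weight_fractions = weight_fractions),
            class = "fit_config")
}

expand_sigma <- function(sigma, B) {
  if (length(sigma) == 1L) rep(as.numeric(sigma), B) else as.numeric(sigma)
}

cpp_passes <- function(max_passes) {
  as.integer(min(max_passes, 10000L))
}

# Greedy climb from a given sequence under optional subject weights.
improve_sequence <- function(Z, events, sigma, weights = NULL,
                             max_passes = Inf) {
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  res <- cpp_greedy_improve(Z, as.integer(events),
                            expand_sigma(sigma, ncol(Z)), weights,
                            cpp_passes(max_passes))
  list(events = as.integer(res$seq), loglik = res$loglik)
}

#' Fit a single-subtype event sequence
#'
#' Multi-start greedy hill climbing: each restart draws a random valid
#' sequence and relocates single events (best improvement, ties to the first
#' found) until no move increases the data log-likelihood; the best restart
#' wins. Deterministic for a given seed.
#'
#' @param Z z-score matrix (subjects x biomarkers), at least 2 subjects.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param weights optional per-subject weights (EM responsibilities).
#' @param init optional starting sequence evaluated alongside the random
#'   restarts.
#' @return list with `events` (the fitted sequence) and `loglik`.
#' @export
fit_single_subtype <- function(Z, config = fit_config(), seed = 1,
                               weights = NULL, init = NULL) {
  Z <- as.matrix(Z)
  if (is.null(weights) && nrow(Z) < 2L) stop("need at least 2 subjects")
  B <- ncol(Z)
  starts <- with_local_seed(child_seed(seed, "single-subtype-starts"), {
    lapply(seq_len(config$restarts), function(i) random_valid_sequence(B))
  })
  if (!is.null(init)) starts <- c(list(as.integer(init)), starts)
  best <- NULL
  for (s in starts) {
    res <- improve_sequence(Z, s, config$sigma, weights, config$max_passes)
    if (is.null(best) || res$loglik > best$loglik + 1e-9) best <- res
  }
  best
}

em_refine <- function(Z, sequences, fractions, panel, config,
                      max_iter = config$em_max_iter) {
  C <- length(sequences)
  model <- sustain_model(sequences, fractions, panel, config$sigma)
  ll <- data_log_likelihood(Z, model)
  for (iter in seq_len(max_iter)) {
    LM <- subtype_log_marginals(Z, model)
    R <- sweep(LM, 2L, log(pmax(model$fractions, 1e-300)), `+`)
    R <- exp(R - log_row_sum_exp(R))
    fractions <- colMeans(R)
    sequences <- lapply(seq_len(C), function(c) {
      w <- R[, c]
      if (sum(w) < 1e-8) return(model$sequences[[c]]) # empty subtype: freeze
      improve_sequence(Z, model$sequences[[c]], config$sigma, w,
                       min(config$em_passes, config$max_passes))$events
    })
    model <- sustain_model(sequences, fractions, panel, config$sigma)
    ll_new <- data_log_likelihood(Z, model)
    if (ll_new - ll < config$em_tol) {
      ll <- max(ll, ll_new)
      break
    }
    ll <- ll_new
  }
  list(model = model, loglik = ll)
}

#' Fit a multi-subtype progression model
#'
#' Hierarchical split-and-refit: the C-subtype model is initialized from the
#' (C-1)-subtype model by randomly bipartitioning each cluster's
#' maximum-likelihood members, fitting a fresh sequence on each half, and
#' keeping the best candidate after alternating (a) responsibility-weighted
#' sequence optimization and (b) fraction updates (the mean responsibility)
#' until the log-likelihood gain falls below tolerance.
#'
#' @param Z z-score matrix.
#' @param n_subtypes number of subtypes C, 1 to 5.
#' @param panel a `sustain_panel` matching the columns of `Z`.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param return_all return the whole hierarchy of models 1..C instead of the
#'   C-subtype model only.
#' @return a `sustain_model` (or a list of them when `return_all = TRUE`),
#'   each carrying its training `loglik` attribute.
#' @export
fit_sustain <- function(Z, n_subtypes, panel = default_panel(),
                        config = fit_config(), seed = 1, return_all = FALSE) {
  Z <- as.matrix(Z)
  if (n_subtypes > 5) stop("the maximum number of subtypes is 5")
  stopifnot(n_subtypes >= 1)
  if (nrow(Z) < n_subtypes) stop("fewer subjects than subtypes")
  B <- ncol(Z)
  stopifnot(panel$n_biomarkers == B)

  # same seed path as a direct single-subtype fit, so C = 1 reduces exactly
  single <- fit_single_subtype(Z, config, seed = seed)
  m1 <- sustain_model(list(single$events), 1, panel, config$sigma)
  attr(m1, "loglik") <- data_log_likelihood(Z, m1)
  models <- list(m1)

  for (C in seq_len(n_subtypes)[-1]) {
    base <- models[[C - 1L]]
    resp <- subtype_responsibilities(Z, base)
    hard <- max.col(resp, ties.method = "first")
    cands <- list()
    for (cc in seq_len(C - 1L)) {
      members <- which(hard == cc)
      if (length(members) < 4L) next
      pairs <- split_candidates(Z[members, , drop = FALSE],
                                base$sequences[[cc]], config,
                                seed = child_seed(seed, sprintf("c%d-split%d", C, cc)))
      for (t in seq_along(pairs)) {
        pr <- pairs[[t]]
        seqs <- c(base$sequences[-cc], list(pr$seq_a, pr$seq_b))
        f_cc <- base$fractions[cc]
        fr <- c(base$fractions[-cc],
                f_cc * pr$frac_a, f_cc * (1 - pr$frac_a))
        fr <- fr / sum(fr)
        cands[[length(cands) + 1L]] <-
          em_refine(Z, seqs, fr, panel, config,
                    max_iter = config$em_candidate_iter)
      }
    }
    if (length(cands) == 0L) {
      stop("could not split any cluster when growing to ", C, " subtypes")
    }
    # near-tied screening candidates can finish in different basins:
    # refine the best few fully and keep the likelihood winner
    ord <- order(vapply(cands, `[[`, numeric(1), "loglik"), decreasing = TRUE)
    best <- NULL
    for (i in utils::head(ord, config$n_finalists)) {
      full <- em_refine(Z, cands[[i]]$model$sequences,
                        cands[[i]]$model$fractions, panel, config)
      full <- hard_refit(Z, full, panel, config,
                         seed = child_seed(seed, paste0("refine-c", C, "-f", i)))
      if (is.null(best) || full$loglik > best$loglik + 1e-9) best <- full
    }
    mC <- best$model
    attr(mC, "loglik") <- best$loglik
    models[[C]] <- mC
  }

  if (return_all) models else models[[n_subtypes]]
}

#' Refine a fitted model with a stronger optimization budget
#'
#' Reruns the alternating refinement and hard-assignment refit cycles on an
#' existing model under a (typically stronger) configuration; useful to
#' polish one subtype count of a hierarchy fitted with a light budget.
#'
#' @param Z z-score matrix the model was fitted on.
#' @param model a `sustain_model`.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return the refined `sustain_model` with its `loglik` attribute.
#' @export
refine_model <- function(Z, model, config = fit_config(), seed = 1) {
  Z <- as.matrix(Z)
  best <- em_refine(Z, model$sequences, model$fractions, model$panel, config)
  best <- hard_refit(Z, best, model$panel, config,
                     seed = child_seed(seed, "refine-model"))
  m <- best$model
  attr(m, "loglik") <- best$loglik
  m
}

# Hard-assignment refit: escape weighted-move local optima by refitting each
# subtype's sequence from scratch on its hard-assigned members, then
# realternating; kept only on improvement. Small clusters (where a minority
# trajectory's sequence is cheap to refit well) get the full restart budget.
hard_refit <- function(Z, best, panel, config, seed) {
  C <- best$model$n_subtypes
  for (cycle in seq_len(config$refine_cycles)) {
    m <- best$model
    h <- max.col(subtype_responsibilities(Z, m), ties.method = "first")
    newseqs <- lapply(seq_len(C), function(cc) {
      idx <- which(h == cc)
      if (length(idx) < 2L) return(m$sequences[[cc]])
      rcfg <- config
      rcfg$restarts <- if (length(idx) <= 100L) config$restarts else
        config$split_restarts
      fit_single_subtype(Z[idx, , drop = FALSE], rcfg,
                         seed = child_seed(seed, paste0("cycle", cycle, "-", cc)),
                         weights = rep(1, length(idx)),
                         init = m$sequences[[cc]])$events
    })
    cand <- em_refine(Z, newseqs, m$fractions, panel, config)
    if (cand$loglik > best$loglik + 1e-9) best <- cand else break
  }
  best
}

# Candidate child-sequence pairs for splitting one cluster when growing the
# subtype count. Each candidate is a pair of starting sequences (plus a
# fraction split) for the two children:
#  - `split_tries` random coin-flip bipartitions, both halves fitted fresh;
#  - worst-fit splits at the 5%, 10% and 25% marginal-likelihood quantiles: the
#    poorly-fitting members (where any minority trajectory hiding in the
#    cluster concentrates) get a fresh sequence while the rest keep the
#    cluster's current sequence;
#  - a 2-means bipartition of stage-residual patterns, both halves fitted.
split_candidates <- function(Zc, events, config, seed) {
  n <- nrow(Zc)
  sig <- expand_sigma(config$sigma, ncol(Zc))
  fit_half <- function(rows, tag) {
    half_cfg <- config
    # small subsets (where minority trajectories live) are cheap to fit
    # well, so they get the full restart budget
    half_cfg$restarts <- if (sum(rows) <= 100L) config$restarts else
      config$split_restarts
    fit_single_subtype(Zc[rows, , drop = FALSE], half_cfg,
                       seed = child_seed(seed, tag), weights = rep(1, sum(rows)))
  }
  pairs <- list()

  rand_groups <- with_local_seed(child_seed(seed, "random"), {
    lapply(seq_len(config$split_tries), function(t) {
      g <- stats::runif(n) < 0.5
      if (all(g) || all(!g)) g[1L] <- !g[1L]
      g
    })
  })
  for (t in seq_along(rand_groups)) {
    g <- rand_groups[[t]]
    pairs[[length(pairs) + 1L]] <- list(
      seq_a = fit_half(g, paste0("rand", t, "a"))$events,
      seq_b = fit_half(!g, paste0("rand", t, "b"))$events,
      frac_a = mean(g))
  }

  lm <- seq_log_marginals(Zc, events, sig)
  for (q in c(0.05, 0.10, 0.25)) {
    worst <- lm <= stats::quantile(lm, q)
    if (sum(worst) >= 2L && sum(!worst) >= 2L) {
      pairs[[length(pairs) + 1L]] <- list(
        seq_a = events, # well-fitting members keep the parent sequence
        seq_b = fit_half(worst, paste0("worst", round(100 * q)))$events,
        frac_a = mean(!worst))
    }
  }

  E <- seq_expected(events, ncol(Zc))
  L <- stage_loglik_matrix(Zc, E, sig)
  stage <- max.col(L, ties.method = "first")
  resid <- Zc - E[stage, , drop = FALSE]
  km <- with_local_seed(child_seed(seed, "kmeans"), {
    tryCatch(stats::kmeans(resid, centers = 2L, nstart = 2L),
             error = function(e) NULL)
  })
  if (!is.null(km) && min(km$size) >= 2L) {
    g <- km$cluster == 1L
    pairs[[length(pairs) + 1L]] <- list(
      seq_a = fit_half(g, "kma")$events,
      seq_b = fit_half(!g, "kmb")$events,
      frac_a = mean(g))
  }
  pairs
}

# n x C posterior subtype responsibilities under a fitted model.
subtype_responsibilities <- function(Z, model) {
  LM <- subtype_log_marginals(Z, model)
  R <- sweep(LM, 2L, log(pmax(model$fractions, 1e-300)), `+`)
  exp(R - log_row_sum_exp(R))
}

#' Select the number of subtypes by cross-validation information criterion
#'
#' K-fold CVIC: for each candidate subtype count C, a model is fitted on
#' each fold's training part and scored by -2 times the held-out data
#' log-likelihood summed over folds. The held-out likelihood is evaluated
#' under each subtype's positional-uncertainty ensemble (Metropolis samples
#' of the sequence drawn on the training part), not the point sequence
#' alone: point-sequence scoring lets a duplicate subtype hedge sequence
#' uncertainty and systematically favours spurious extra subtypes. Fold
#' models are initialized from a full-data hierarchical fit and EM-refined
#' on the fold's training part (their parameters depend on the training part
#' only). The selected C is the smallest whose CVIC lies within one paired
#' standard error of the minimum; the raw argmin is also reported. Folds are
#' seeded and stratified by diagnosis when labels are supplied.
#'
#' @param Z z-score matrix.
#' @param max_subtypes largest C considered (at most 5).
#' @param folds number of folds (>= 2).
#' @param panel a `sustain_panel`.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param diagnosis optional per-subject labels for stratified folds.
#' @param init_models optional list of models 1..max_subtypes from
#'   [fit_sustain()] with `return_all = TRUE`, reused as warm starts
#'   (otherwise fitted here).
#' @param mcmc_iter,mcmc_thin Metropolis budget per subtype per fold for the
#'   ensemble evaluation.
#' @return list with `cvic` (per-C scores), `selected` C (parsimony rule),
#'   `selected_min` (argmin), the per-fold score matrix and fold ids.
#' @export
cvic_select <- function(Z, max_subtypes = 5, folds = 10,
                        panel = default_panel(), config = fit_config(),
                        seed = 1, diagnosis = NULL, init_models = NULL,
                        mcmc_iter = 2000, mcmc_thin = 20) {
  Z <- as.matrix(Z)
  if (max_subtypes > 5) stop("the maximum number of subtypes is 5")
  stopifnot(folds >= 2)
  n <- nrow(Z)
  if (floor(n / folds) < max_subtypes) {
    stop("too few subjects per fold for ", max_subtypes, " subtypes")
  }
  fold_id <- with_local_seed(child_seed(seed, "cvic-folds"), {
    id <- integer(n)
    if (is.null(diagnosis)) {
      id <- sample(rep_len(seq_len(folds), n))
    } else {
      for (g in unique(diagnosis)) {
        idx <- which(diagnosis == g)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    }
    id
  })

  if (is.null(init_models)) {
    init_models <- fit_sustain(Z, max_subtypes, panel, config,
                               seed = child_seed(seed, "cvic-full"),
                               return_all = TRUE)
  }
  stopifnot(length(init_models) >= max_subtypes)

  per_fold <- matrix(NA_real_, nrow = folds, ncol = max_subtypes,
                     dimnames = list(NULL, paste0("C", seq_len(max_subtypes))))
  for (f in seq_len(folds)) {
    train <- fold_id != f
    Ztr <- Z[train, , drop = FALSE]
    Zte <- Z[!train, , drop = FALSE]
    for (C in seq_len(max_subtypes)) {
      init <- init_models[[C]]
      ref <- em_refine(Ztr, init$sequences, init$fractions, panel, config)
      ref <- hard_refit(Ztr, ref, panel, config,
                        seed = child_seed(seed, paste0("cvic-f", f, "c", C)))
      per_fold[f, C] <- -2 * ensemble_heldout_loglik(
        Ztr, Zte, ref$model, mcmc_iter, mcmc_thin,
        seed = child_seed(seed, paste0("cvic-mc-f", f, "c", C)))
    }
  }
  cvic <- colSums(per_fold)
  sel_min <- unname(which.min(cvic))
  # parsimony: smallest C within one paired SE of the minimum
  selected <- sel_min
  for (C in seq_len(sel_min)) {
    d <- per_fold[, C] - per_fold[, sel_min]
    if (sum(d) <= stats::sd(d) * sqrt(folds) + 1e-9) {
      selected <- C
      break
    }
  }
  list(cvic = cvic, selected = selected, selected_min = sel_min,
       per_fold = per_fold, fold_id = fold_id)
}

# Held-out log-likelihood under the positional-uncertainty ensemble: each
# subtype's sequence posterior is approximated by Metropolis samples drawn
# on the training part (responsibility-weighted), and the held-out marginal
# averages over them before mixing across subtypes.
ensemble_heldout_loglik <- function(Ztr, Zte, model, mcmc_iter, mcmc_thin,
                                    seed) {
  C <- model$n_subtypes
  R <- subtype_responsibilities(Ztr, model)
  log_margs <- matrix(NA_real_, nrow(Zte), C)
  for (cc in seq_len(C)) {
    samp <- sequence_uncertainty(Ztr, model$sequences[[cc]], model$sigma,
                                 weights = R[, cc], iterations = mcmc_iter,
                                 thin = mcmc_thin,
                                 seed = child_seed(seed, paste0("sub", cc)))
    keys <- vapply(samp$samples, paste, character(1), collapse = ",")
    uk <- unique(keys)
    wts <- as.numeric(table(keys)[uk]) / length(keys)
    seqs <- samp$samples[match(uk, keys)]
    LM <- vapply(seqs, function(s) seq_log_marginals(Zte, s, model$sigma),
                 numeric(nrow(Zte)))
    LM <- matrix(LM, nrow = nrow(Zte))
    log_margs[, cc] <- log_row_sum_exp(sweep(LM, 2L, log(wts), `+`))
  }
  wl <- sweep(log_margs, 2L, log(pmax(model$fractions, 1e-300)), `+`)
  sum(log_row_sum_exp(wl))
}

#' Assign a subject to a subtype and stage
#'
#' The subject's subtype is the one maximizing the (fraction-weighted) stage
#' marginal of its z-scores, and the stage is the maximum-likelihood stage
#' under that subtype (ties broken toward the lower stage and lower subtype
#' index). Subjects landing on stage 0 or the final stage N receive an
#' undefined (NA) subtype, since those stages are identical under every
#' subtype and carry no subtype information.
#'
#' @param model a `sustain_model`.
#' @param z a single z-vector or a z-score matrix (subjects x biomarkers).
#' @param weight_fractions weight marginals by mixture fractions (default
#'   TRUE).
#' @return for a matrix, a data.frame with columns `subtype`, `stage`,
#'   `stage_ml` plus a `"posterior"` attribute (subjects x subtypes x
#'   stages); for a vector, a one-row result.
#' @export
assign_subjects <- function(model, z, weight_fractions = TRUE) {
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  n <- nrow(Z)
  C <- model$n_subtypes
  N <- model$n_stages
  post <- array(NA_real_, dim = c(n, C, N + 1L))
  logmarg <- matrix(NA_real_, n, C)
  stage_ml <- matrix(NA_integer_, n, C)
  for (cc in seq_len(C)) {
    E <- seq_expected(model$sequences[[cc]], model$panel$n_biomarkers)
    L <- stage_loglik_matrix(Z, E, model$sigma)
    logmarg[, cc] <- log_row_sum_exp(L) - log(N + 1L)
    stage_ml[, cc] <- max.col(L, ties.method = "first") - 1L
    post[, cc, ] <- exp(L)
  }
  wl <- if (weight_fractions) {
    sweep(logmarg, 2L, log(pmax(model$fractions, 1e-300)), `+`)
  } else logmarg
  subtype <- max.col(wl, ties.method = "first")
  stage <- stage_ml[cbind(seq_len(n), subtype)]

  # joint posterior over (subtype, stage), fraction-weighted
  w <- if (weight_fractions) model$fractions else rep(1 / C, C)
  for (i in seq_len(n)) {
    mp <- matrix(post[i, , ], nrow = C) * w # w recycles down subtype rows
    post[i, , ] <- mp / sum(mp)
  }

  undefined <- stage %in% c(0L, N)
  out <- data.frame(subtype = ifelse(undefined, NA_integer_, subtype),
                    stage = stage)
  out$stage_ml <- stage
  rownames(out) <- rownames(Z)
  attr(out, "posterior") <- post
  attr(out, "log_marginals") <- logmarg
  out
}

#' Positional uncertainty of a fitted sequence
#'
#' Metropolis sampling over valid single-event relocations around a fitted
#' sequence, thinned, summarised as the probability of each event occupying
#' each sequence position. Used for reporting uncertainty shading only; point
#' estimates always come from the greedy fit.
#'
#' @param Z z-score matrix.
#' @param events fitted sequence.
#' @param sigma noise SD (scalar or per-biomarker).
#' @param weights optional subject weights.
#' @param iterations,thin MCMC length and thinning.
#' @param seed integer seed.
#' @return list with `position_prob` (events x positions matrix), the
#'   thinned `samples` (list of sequences) and the acceptance rate.
#' @export
sequence_uncertainty <- function(Z, events, sigma = 1, weights = NULL,
                                 iterations = 10000, thin = 10, seed = 1) {
  Z <- as.matrix(Z)
  B <- ncol(Z)
  N <- length(events)
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  sig <- expand_sigma(sigma, B)
  samples <- vector("list", iterations %/% thin)
  counts <- matrix(0, N, N, dimnames = list(event = NULL, position = NULL))
  with_local_seed(child_seed(seed, "sequence-mcmc"), {
    cur <- as.integer(events)
    cur_ll <- cpp_seq_score(Z, cur, sig, weights)
    accepted <- 0L
    for (it in seq_len(iterations)) {
      i <- sample.int(N, 1L)
      pos <- seq_positions(cur, B)
      id <- cur[i]
      b <- event_biomarker(id); l <- event_level(id)
      q1 <- if (l > 1L) pos[b, l - 1L] else 0L
      q2 <- if (l < 3L) pos[b, l + 1L] else N + 1L
      targets <- setdiff(seq(q1 + 1L, q2 - 1L), i)
      if (length(targets) > 0L) {
        j <- targets[sample.int(length(targets), 1L)]
        prop <- append(cur[-i], id, after = j - 1L)
        prop_ll <- cpp_seq_score(Z, prop, sig, weights)
        # Hastings correction: the reverse move chooses among the proposal
        # state's valid targets for the same event
        pos_p <- seq_positions(prop, B)
        r1 <- if (l > 1L) pos_p[b, l - 1L] else 0L
        r2 <- if (l < 3L) pos_p[b, l + 1L] else N + 1L
        n_rev <- (r2 - r1 - 2L)
        log_ratio <- prop_ll - cur_ll + log(length(targets)) - log(n_rev)
        if (log(stats::runif(1)) < log_ratio) {
          cur <- prop
          cur_ll <- prop_ll
          accepted <- accepted + 1L
        }
      }
      if (it %% thin == 0L) {
        p <- integer(N); p[cur] <- seq_len(N)
        counts[cbind(seq_len(N), p)] <- counts[cbind(seq_len(N), p)] + 1
        samples[[it %/% thin]] <- cur
      }
    }
    list(position_prob = counts / max(1, sum(counts[1L, ])),
         samples = samples,
         acceptance_rate = accepted / iterations)
  })
}
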