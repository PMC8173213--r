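#' @name event-sequences
#' @title Event sequences
#'
#' @description
#' An event sequence is an ordering of the N = 3B z-score events of a
#' B-biomarker panel. Event (b, l) is the moment biomarker b's
#' control-referenced z-score reaches integer level l. A sequence is valid
#' when every (biomarker, level) pair appears exactly once and, for each
#' biomarker, level 1 precedes level 2 precedes level 3. Internally events
#' are coded as integer ids `(b - 1) * 3 + l`.
NULL

event_id <- function(biomarker, level) {
  (as.integer(biomarker) - 1L) * 3L + as.integer(level)
}
event_biomarker <- function(id) (id - 1L) %/% 3L + 1L
event_level <- function(id) (id - 1L) %% 3L + 1L

#' Build an event sequence from biomarker/level vectors
#'
#' @param biomarker integer biomarker indices (1-based into the panel).
#' @param level integer z-score levels in 1..3.
#' @param n_biomarkers panel size B.
#' @return integer vector of event ids, validated.
#' @export
event_sequence <- function(biomarker, level, n_biomarkers) {
  events <- event_id(as.integer(biomarker), as.integer(level))
  validate_sequence(events, n_biomarkers)
  events
}

#' Check sequence validity
#'
#' @param events integer event-id vector.
#' @param n_biomarkers panel size B.
#' @return invisibly TRUE; errors when invalid.
#' @export
validate_sequence <- function(events, n_biomarkers) {
  n <- 3L * n_biomarkers
  if (length(events) != n || !setequal(events, seq_len(n))) {
    stop("sequence must contain each of the ", n, " (biomarker, level) events exactly once")
  }
  pos <- seq_positions(events, n_biomarkers)
  if (any(pos[, 1] >= pos[, 2]) || any(pos[, 2] >= pos[, 3])) {
    stop("within each biomarker, level-1 must precede level-2 must precede level-3")
  }
  invisible(TRUE)
}

is_valid_sequence <- function(events, n_biomarkers) {
  n <- 3L * n_biomarkers
  if (length(events) != n || anyDuplicated(events) || any(events < 1L) || any(events > n)) {
    return(FALSE)
  }
  pos <- seq_positions(events, n_biomarkers)
  all(pos[, 1] < pos[, 2]) && all(pos[, 2] < pos[, 3])
}

#' Event positions by biomarker and level
#'
#' @param events integer event-id vector.
#' @param n_biomarkers panel size B.
#' @return B x 3 integer matrix; `[b, l]` is the 1-based position of event
#'   (b, l) in the sequence.
#' @export
seq_positions <- function(events, n_biomarkers) {
  pos <- integer(3L * n_biomarkers)
  pos[events] <- seq_along(events)
  matrix(pos, nrow = n_biomarkers, ncol = 3L, byrow = TRUE)
}

#' Expected z-score of a biomarker at a model stage
#'
#' Trajectories progress linearly between events: the expected z-score is the
#' piecewise-linear interpolant through (0, 0), (p1, 1), (p2, 2), (p3, 3),
#' where pl is the position of the biomarker's level-l event, and plateaus at
#' the maximum abnormality z = 3 for stages at or beyond p3.
#'
#' @param events event sequence.
#' @param stage integer stage in 0..N.
#' @param biomarker biomarker index (1-based) or vector of indices.
#' @param n_biomarkers panel size B.
#' @return expected z-score(s).
#' @export
#' @examples
#' s <- event_sequence(c(1, 2, 1, 2, 1, 2), c(1, 1, 2, 2, 3, 3), 2)
#' expected_zscore(s, 4, 1, 2) # 2.5: midway between positions 3 and 5
expected_zscore <- function(events, stage, biomarker, n_biomarkers) {
  stopifnot(stage >= 0, stage <= length(events))
  if (any(biomarker < 1L) || any(biomarker > n_biomarkers)) {
    stop("biomarker index out of panel range")
  }
  pos <- seq_positions(events, n_biomarkers)
  E <- expected_matrix(pos, length(events))
  E[stage + 1L, biomarker]
}

# Full (N + 1) x B matrix of expected z-scores over stages 0..N.
# Vectorized piecewise-linear evaluation; hot path of all likelihoods.
expected_matrix <- function(pos, n_stages) {
  B <- nrow(pos)
  k <- matrix(0:n_stages, nrow = n_stages + 1L, ncol = B)
  p1 <- matrix(pos[, 1], nrow = n_stages + 1L, ncol = B, byrow = TRUE)
  p2 <- matrix(pos[, 2], nrow = n_stages + 1L, ncol = B, byrow = TRUE)
  p3 <- matrix(pos[, 3], nrow = n_stages + 1L, ncol = B, byrow = TRUE)
  E <- ifelse(k <= p1, k / p1,
       ifelse(k <= p2, 1 + (k - p1) / (p2 - p1),
       ifelse(k <= p3, 2 + (k - p2) / (p3 - p2), 3)))
  E
}

#' Draw a random valid sequence
#'
#' Each event receives an independent uniform key; within every biomarker the
#' sorted keys are assigned to levels 1 < 2 < 3, and events are ordered by
#' key. Uses the current RNG state.
#'
#' @param n_biomarkers panel size B.
#' @return a valid event sequence.
#' @export
random_valid_sequence <- function(n_biomarkers) {
  keys <- matrix(stats::runif(3L * n_biomarkers), nrow = n_biomarkers)
  keys <- t(apply(keys, 1L, sort))
  ids <- matrix(event_id(rep(seq_len(n_biomarkers), 3L), rep(1:3, each = n_biomarkers)),
                nrow = n_biomarkers)
  order_keys <- order(as.vector(t(keys)))
  as.vector(t(ids))[order_keys]
}

#' Enumerate every valid sequence of a small panel
#'
#' Exhaustive enumeration of all orderings respecting the per-biomarker level
#' constraint; there are (3B)! / (3!)^B of them (20 for B = 2). Intended for
#' oracle checks on toy panels only.
#'
#' @param n_biomarkers panel size B (at most 3).
#' @return list of event sequences.
#' @export
enumerate_sequences <- function(n_biomarkers) {
  stopifnot(n_biomarkers <= 3L)
  n <- 3L * n_biomarkers
  res <- list()
  recurse <- function(prefix, remaining_level) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(n_biomarkers)) {
      if (remaining_level[b] <= 3L) {
        nl <- remaining_level
        nl[b] <- nl[b] + 1L
        recurse(c(prefix, event_id(b, remaining_level[b])), nl)
      }
    }
  }
  recurse(integer(0), rep(1L, n_biomarkers))
  res
}

#' Kendall rank correlation between two event sequences
#'
#' Compares the event orderings of two sequences via the Kendall tau of their
#' event positions; 1 means identical ordering, -1 fully reversed. Used to
#' score how well a fitted sequence recovers a ground-truth one.
#'
#' @param seq_a,seq_b event sequences over the same panel.
#' @return Kendall's tau in [-1, 1].
#' @export
sequence_kendall_tau <- function(seq_a, seq_b) {
  stopifnot(length(seq_a) == length(seq_b))
  pos_a <- integer(length(seq_a)); pos_a[seq_a] <- seq_along(seq_a)
  pos_b <- integer(length(seq_b)); pos_b[seq_b] <- seq_along(seq_b)
  unname(stats::cor(pos_a, pos_b, method = "kendall"))
}
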