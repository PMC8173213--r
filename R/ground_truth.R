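#' Ground truth for synthetic cohorts
#'
#' A `sustain_truth` object fixes everything the generator needs: the true
#' event sequence of each subtype, the mixing fractions, stage distributions
#' by diagnosis, the control-scale volume distribution of each region,
#' linear covariate effects on raw volumes, the MMSE decline per stage, the
#' two-component CSF amyloid mixture around the 192 pg/ml cut-off, and the
#' longitudinal stage drift (stages per 12 months).
#'
#' With three subtypes on the default 13-region panel the sequences mimic the
#' canonical atrophy subtypes: (1) a typical pattern with early ventricular,
#' hippocampal and entorhinal events and late full ventricular abnormality;
#' (2) a pattern starting in thalamus and pallidum with later medial-temporal
#' involvement; (3) a pattern in which the ventricles become fully abnormal
#' before atrophy spreads elsewhere. Default fractions are 0.65/0.30/0.05 and
#' the default drift is 0.8 +/- 1.5 stages per 12 months.
#'
#' @param n_subtypes number of true subtypes, 1 to 5 (the model family caps
#'   the subtype count at 5).
#' @param panel a `sustain_panel`; defaults to [default_panel()].
#' @param seed integer seed; only consumed when sequences must be drawn
#'   (panels or subtype counts without handcrafted defaults).
#' @return an object of class `sustain_truth`.
#' @export
#' @examples
#' gt <- make_ground_truth(3, default_panel(), seed = 1)
#' lengths(gt$sequences) # 39 39 39
make_ground_truth <- function(n_subtypes = 3, panel = default_panel(), seed = 1) {
  stopifnot(n_subtypes >= 1)
  if (n_subtypes > 5) {
    stop("the maximum number of subtypes is 5")
  }
  if (panel$n_biomarkers < 2) stop("panel must have at least 2 biomarkers")

  sequences <- default_sequences(n_subtypes, panel, seed)
  for (s in sequences) validate_sequence(s, panel$n_biomarkers)
  if (n_subtypes > 1) {
    for (i in seq_len(n_subtypes - 1)) {
      for (j in seq(i + 1, n_subtypes)) {
        if (identical(sequences[[i]], sequences[[j]])) {
          stop("ground-truth sequences must be mutually distinct")
        }
      }
    }
  }

  fractions <- default_fractions(n_subtypes)
  N <- panel$n_events

  structure(
    list(
      panel = panel,
      n_subtypes = n_subtypes,
      sequences = sequences,
      fractions = fractions,
      stage_dist = default_stage_dists(N),
      control_mean = default_control_means(panel),
      control_sd = default_control_sds(panel),
      covariate_effects = default_covariate_effects(panel),
      covariate_reference = c(age = 72, sex = 0.5, education = 15,
                              apoe4 = 0.4, tiv = 1.4e6),
      mmse_slope = 0.4,
      mmse_sd = 1.5,
      csf_params = list(
        negative = c(mean = 250, sd = 35), # amyloid-negative component, pg/ml
        positive = c(mean = 140, sd = 30), # amyloid-positive component, pg/ml
        cutoff = 192
      ),
      drift_mean = 0.8,
      drift_sd = 1.5,
      seed = seed
    ),
    class = "sustain_truth"
  )
}

#' @export
print.sustain_truth <- function(x, ...) {
  cat("Synthetic ground truth:", x$n_subtypes, "subtype(s),",
      x$panel$n_events, "stages\n")
  cat("  fractions:", paste(sprintf("%.2f", x$fractions), collapse = "/"), "\n")
  cat("  drift    :", x$drift_mean, "+/-", x$drift_sd, "stages / 12 months\n")
  invisible(x)
}

default_fractions <- function(n_subtypes) {
  if (n_subtypes == 1) return(1)
  if (n_subtypes == 3) return(c(0.65, 0.30, 0.05))
  f <- 2^-(seq_len(n_subtypes) - 1)
  f / sum(f)
}

# Handcrafted sequences for the default 13-region panel (three canonical
# atrophy patterns); otherwise seeded staggered-onset random orderings.
default_sequences <- function(n_subtypes, panel, seed) {
  nm <- panel$names
  B <- panel$n_biomarkers
  canonical <- identical(nm, default_panel()$names)
  if (canonical && n_subtypes <= 3) {
    ev <- function(region, level) event_id(match(region, nm), level)
    typical <- c(
      ev("ventricles", 1), ev("hippocampus", 1), ev("entorhinal", 1),
      ev("amygdala", 1), ev("hippocampus", 2), ev("entorhinal", 2),
      ev("middle_temporal", 1), ev("fusiform", 1), ev("amygdala", 2),
      ev("hippocampus", 3), ev("entorhinal", 3), ev("amygdala", 3),
      ev("precuneus", 1), ev("insula", 1), ev("middle_temporal", 2),
      ev("fusiform", 2), ev("ventricles", 2), ev("thalamus", 1),
      ev("putamen", 1), ev("caudate", 1), ev("middle_temporal", 3),
      ev("fusiform", 3), ev("precuneus", 2), ev("insula", 2),
      ev("accumbens", 1), ev("pallidum", 1), ev("precuneus", 3),
      ev("insula", 3), ev("thalamus", 2), ev("putamen", 2),
      ev("caudate", 2), ev("accumbens", 2), ev("pallidum", 2),
      ev("thalamus", 3), ev("putamen", 3), ev("caudate", 3),
      ev("accumbens", 3), ev("pallidum", 3), ev("ventricles", 3)
    )
    subcortical_first <- c(
      ev("thalamus", 1), ev("pallidum", 1), ev("caudate", 1),
      ev("putamen", 1), ev("thalamus", 2), ev("pallidum", 2),
      ev("insula", 1), ev("precuneus", 1), ev("caudate", 2),
      ev("putamen", 2), ev("fusiform", 1), ev("middle_temporal", 1),
      ev("hippocampus", 1), ev("thalamus", 3), ev("pallidum", 3),
      ev("insula", 2), ev("precuneus", 2), ev("caudate", 3),
      ev("putamen", 3), ev("hippocampus", 2), ev("fusiform", 2),
      ev("middle_temporal", 2), ev("hippocampus", 3), ev("amygdala", 1),
      ev("entorhinal", 1), ev("insula", 3), ev("precuneus", 3),
      ev("fusiform", 3), ev("middle_temporal", 3), ev("ventricles", 1),
      ev("amygdala", 2), ev("entorhinal", 2), ev("accumbens", 1),
      ev("ventricles", 2), ev("amygdala", 3), ev("entorhinal", 3),
      ev("accumbens", 2), ev("accumbens", 3), ev("ventricles", 3)
    )
    others <- setdiff(nm, "ventricles")
    ventricles_first <- unname(c(
      ev("ventricles", 1), ev("ventricles", 2), ev("ventricles", 3),
      vapply(others, ev, integer(1), level = 1),
      vapply(others, ev, integer(1), level = 2),
      vapply(others, ev, integer(1), level = 3)
    ))
    return(unname(list(typical, subcortical_first, ventricles_first)[seq_len(n_subtypes)]))
  }
  # Generic panels: each subtype gets a seeded biomarker priority order and a
  # staggered onset, so early-priority regions reach level 3 before
  # late-priority regions start (distinct, well-separated patterns).
  with_local_seed(child_seed(seed, "ground-truth-sequences"), {
    lapply(seq_len(n_subtypes), function(s) {
      priority <- sample(B)
      score <- outer(priority, (0:2) * (B * 0.6), "+") +
        matrix(stats::runif(3L * B, 0, 0.25), nrow = B)
      score <- t(apply(score, 1L, sort))
      ids <- matrix(event_id(rep(seq_len(B), 3L), rep(1:3, each = B)), nrow = B)
      as.vector(t(ids))[order(as.vector(t(score)))]
    })
  })
}

# Stage distributions by diagnosis (discrete over 0..N). CN favours the
# lowest stages (truncated geometric), MCI and AD are discretized normals
# mirroring the ordering of group-average stages in cohort studies.
default_stage_dists <- function(n_stages) {
  stages <- 0:n_stages
  cn <- 0.7 * (1 - 0.7)^stages
  mci <- stats::dnorm(stages, mean = 6, sd = 4)
  ad <- stats::dnorm(stages, mean = 12, sd = 5)
  list(
    CN = cn / sum(cn),
    MCI = mci / sum(mci),
    AD = ad / sum(ad)
  )
}

# Control-scale bilateral-average volumes (mm^3); ventricles = 3rd + lateral
# sum. Rounded literature-typical segmentation values for older controls.
default_control_means <- function(panel) {
  defaults <- c(
    hippocampus = 3700, fusiform = 9200, entorhinal = 1900,
    middle_temporal = 10500, precuneus = 9300, amygdala = 1500,
    insula = 6600, thalamus = 6800, putamen = 4800, caudate = 3400,
    accumbens = 520, pallidum = 1700, ventricles = 28000
  )
  m <- defaults[panel$names]
  m[is.na(m)] <- 5000
  names(m) <- panel$names
  m
}

default_control_sds <- function(panel) {
  m <- default_control_means(panel)
  sd <- 0.10 * m
  sd["ventricles" == names(sd)] <- 0.25 * m["ventricles" == names(sd)]
  sd
}

# Additive linear confounds on raw volumes per year/indicator/mm^3 of TIV.
# TIV enters with slope mean/reference-TIV, the linearized head-size scaling.
default_covariate_effects <- function(panel) {
  m <- default_control_means(panel)
  eff <- cbind(
    age = -0.004 * m,          # mm^3 lost per year of age
    sex = 0.04 * m,            # male - female offset
    education = 0.0005 * m,    # mm^3 per education year (small)
    apoe4 = -0.01 * m,         # carrier offset
    tiv = m / 1.4e6            # mm^3 per mm^3 TIV
  )
  # ventricular volume grows with age rather than shrinking
  expansion <- panel$direction == "expansion"
  eff[expansion, "age"] <- -eff[expansion, "age"]
  eff[expansion, "apoe4"] <- -eff[expansion, "apoe4"]
  rownames(eff) <- panel$names
  eff
}
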