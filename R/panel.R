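#' Biomarker panel definition
#'
#' A panel is the ordered set of regional volumetric biomarkers entering the
#' progression model, together with the direction in which each becomes
#' abnormal. Atrophy regions are abnormal when *smaller* than controls;
#' the ventricles are the single expansion region, abnormal when *larger*
#' (disease-related ventricular enlargement). Every biomarker passes through
#' the integer z-score severity levels 1, 2 and 3, with 3 the maximum
#' abnormality, so a panel of B regions defines N = 3B model stages.
#'
#' @param names character vector of unique region labels.
#' @param direction character vector, one of `"atrophy"` or `"expansion"`
#'   per region.
#' @return an object of class `sustain_panel`.
#' @export
#' @examples
#' p <- default_panel()
#' p$n_events # 39
biomarker_panel <- function(names, direction) {
  stopifnot(is.character(names), length(names) >= 2L, !anyDuplicated(names))
  direction <- match.arg(direction, c("atrophy", "expansion"), several.ok = TRUE)
  if (length(direction) == 1L) direction <- rep(direction, length(names))
  stopifnot(length(direction) == length(names))
  structure(
    list(
      names = names,
      direction = direction,
      # +1: abnormality grows with the raw value; -1: shrinks with it
      sign = ifelse(direction == "expansion", 1, -1),
      z_levels = 1:3,
      max_z = 3,
      n_biomarkers = length(names),
      n_events = 3L * length(names)
    ),
    class = "sustain_panel"
  )
}

#' Default 13-region panel
#'
#' Hippocampus, fusiform gyrus, entorhinal cortex, middle temporal cortex,
#' precuneus, amygdala, insula, thalamus, putamen, caudate, nucleus
#' accumbens, pallidum (left/right averaged upstream) and ventricles
#' (3rd + lateral, summed upstream). Ventricles are the only expansion
#' region. Yields 39 model stages.
#'
#' @return a `sustain_panel` with 13 regions.
#' @export
default_panel <- function() {
  regions <- c(
    "hippocampus", "fusiform", "entorhinal", "middle_temporal", "precuneus",
    "amygdala", "insula", "thalamus", "putamen", "caudate", "accumbens",
    "pallidum", "ventricles"
  )
  biomarker_panel(regions, ifelse(regions == "ventricles", "expansion", "atrophy"))
}

#' @export
print.sustain_panel <- function(x, ...) {
  cat("Biomarker panel:", x$n_biomarkers, "regions,", x$n_events, "model stages\n")
  cat("  atrophy   :", paste(x$names[x$direction == "atrophy"], collapse = ", "), "\n")
  cat("  expansion :", paste(x$names[x$direction == "expansion"], collapse = ", "), "\n")
  invisible(x)
}
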