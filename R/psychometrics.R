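#' Jacobson-Truax reliable-change threshold
#'
#' Computes the raw-score change that a subject must exceed for the change to
#' be considered statistically reliable (i.e. larger than plausible
#' measurement error), using the classical Jacobson-Truax reliable change
#' index: \eqn{z_{conf} \cdot SD \cdot \sqrt{2 (1 - r_{xx})}}.
#'
#' This is a utility: the pipeline's operational thresholds (3.48 raw points
#' for the SCCS, 56.6 for the KS-II) are configured constants on the
#' instrument specs, not re-derived from this formula.
#'
#' @param sd Standard deviation of the instrument in the reference
#'   population (raw score points, > 0).
#' @param reliability Test reliability (e.g. Cronbach's alpha), in (0, 1].
#' @param confidence Two-sided confidence level for the z quantile
#'   (default 0.95, giving z = 1.959964).
#' @return The reliable-change threshold in raw score points.
#' @examples
#' reliable_change_threshold(10, 0.88)        # ~9.60
#' reliable_change_threshold(10, 1.0)         # 0: no measurement error
#' @export
reliable_change_threshold <- function(sd, reliability, confidence = 0.95) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("invalid-argument: 'sd' must be a single positive number")
  if (!is.numeric(reliability) || length(reliability) != 1L ||
      !is.finite(reliability) || reliability <= 0 || reliability > 1)
    stop("invalid-argument: 'reliability' must be in (0, 1]")
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    stop("invalid-argument: 'confidence' must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  z * sd * sqrt(2 * (1 - reliability))
}

#' Clinical-significance cutoff between two score distributions
#'
#' Computes the cutoff separating a dysfunctional and a functional population
#' on an instrument. `simple_midpoint` is the plain average of the two means,
#' `(mean_a + mean_b) / 2`; `jacobson_c` is the SD-weighted Jacobson-Truax
#' "c" criterion, `(sd_a * mean_b + sd_b * mean_a) / (sd_a + sd_b)`, which
#' lies where the two (normal) densities cross when variances differ.
#'
#' With the published SCC reference distributions (clinical 23.76 / 7.44,
#' non-clinical 44.88 / 11.28), `simple_midpoint` gives 34.32, applied as 34
#' under nearest-integer rounding.
#'
#' @param mean_a,sd_a Mean and SD of the first (e.g. clinical) population.
#' @param mean_b,sd_b Mean and SD of the second (e.g. non-clinical) population.
#' @param method `"simple_midpoint"` or `"jacobson_c"`.
#' @param rounding How `cutoff_applied` is derived from the raw cutoff:
#'   `"nearest"` (round to nearest integer) or `"floor"`.
#' @return An object of class `"cutoff_result"`: a list with `cutoff_raw`,
#'   `cutoff_applied` (integer), `method`, `rounding`.
#' @examples
#' midpoint_cutoff(23.76, 7.44, 44.88, 11.28)  # raw 34.32, applied 34
#' @export
midpoint_cutoff <- function(mean_a, sd_a, mean_b, sd_b,
                            method = c("simple_midpoint", "jacobson_c"),
                            rounding = c("nearest", "floor")) {
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  if (!is.finite(sd_a) || !is.finite(sd_b) || sd_a <= 0 || sd_b <= 0)
    stop("invalid-argument: standard deviations must be positive")
  raw <- switch(method,
    simple_midpoint = (mean_a + mean_b) / 2,
    jacobson_c = (sd_a * mean_b + sd_b * mean_a) / (sd_a + sd_b)
  )
  applied <- switch(rounding,
    nearest = as.integer(round(raw)),
    floor   = as.integer(floor(raw))
  )
  structure(
    list(cutoff_raw = raw, cutoff_applied = applied,
         method = method, rounding = rounding),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cutoff (%s, rounding: %s): raw %.4g, applied %d\n",
              x$method, x$rounding, x$cutoff_raw, x$cutoff_applied))
  invisible(x)
}

#' Instrument specification
#'
#' Bundles the metadata of a measurement instrument used by the pipeline:
#' score range, reliability, the configured reliable-change threshold in raw
#' score points, and score polarity.
#'
#' @param name Instrument name.
#' @param score_min,score_max Score range bounds (`score_min < score_max`).
#' @param rci_threshold Reliable-change threshold in raw points; must be
#'   positive and smaller than the score range. `NA` for instruments on which
#'   no reliable-change decision is made.
#' @param reliability Optional reliability in (0, 1].
#' @param norm_sd Optional reference-population SD.
#' @param higher_is_better Score polarity flag.
#' @return An object of class `"instrument_spec"`.
#' @export
instrument_spec <- function(name, score_min, score_max,
                            rci_threshold = NA_real_,
                            reliability = NA_real_, norm_sd = NA_real_,
                            higher_is_better = TRUE) {
  if (score_min >= score_max)
    stop("invalid-argument: score_min must be smaller than score_max")
  if (!is.na(rci_threshold) &&
      (!is.finite(rci_threshold) || rci_threshold <= 0 ||
       rci_threshold >= (score_max - score_min)))
    stop("invalid-argument: rci_threshold must be in (0, score range)")
  if (!is.na(reliability) && (reliability <= 0 || reliability > 1))
    stop("invalid-argument: reliability must be in (0, 1]")
  if (!is.na(norm_sd) && norm_sd < 0)
    stop("invalid-argument: norm_sd must be >= 0")
  structure(
    list(name = name, score_min = score_min, score_max = score_max,
         rci_threshold = rci_threshold, reliability = reliability,
         norm_sd = norm_sd, higher_is_better = higher_is_better),
    class = "instrument_spec"
  )
}

#' Default instrument battery
#'
#' The three instruments the pipeline expects:
#' * SCCS — 12-item self-concept clarity scale, range 12-60, reliable-change
#'   threshold 3.48 points, higher scores = clearer self-concept;
#' * KS-II — 85-item neurotic symptom checklist (weighted item scoring,
#'   range 0-595), reliable-change threshold 56.6, higher = more symptoms;
#' * KON-2006 — 235-item neurotic personality questionnaire, higher = more
#'   neurotic personality traits.
#'
#' All thresholds are configurable via [instrument_spec()].
#'
#' @return Named list of `"instrument_spec"` objects (`sccs`, `ks2`, `kon`).
#' @export
default_instruments <- function() {
  list(
    sccs = instrument_spec("SCCS", 12, 60, rci_threshold = 3.48,
                           reliability = 0.88, norm_sd = 10,
                           higher_is_better = TRUE),
    ks2  = instrument_spec("KS-II", 0, 595, rci_threshold = 56.6,
                           reliability = 0.97, higher_is_better = FALSE),
    kon  = instrument_spec("KON-2006", 0, 235,
                           reliability = 0.92, higher_is_better = FALSE)
  )
}
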