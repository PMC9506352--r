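#' Aequorin calibration parameters
#'
#' The empirical aequorin calibration curve maps the instantaneous fractional
#' consumption rate k of the photoprotein to pCa:
#' \deqn{pCa = slope \cdot (-\log_{10} k) + intercept}
#' with k in s^-1 computed as luminescence rate divided by total remaining
#' luminescence. The defaults are the field-standard constants for cytosolic
#' aequorin reconstituted with native coelenterazine; both are exposed so an
#' alternative curve can be swapped in.
#'
#' @param slope Dimensionless slope of the pCa vs -log10(k) line.
#' @param intercept Intercept in pCa units.
#' @param k_floor Rate-constant floor (s^-1) applied to zero-count samples so
#'   traces stay on a uniform grid for integration.
#' @param background Constant background counts per integration window,
#'   subtracted before calibration (default 0).
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(slope = 0.332588, intercept = 5.5593,
                               k_floor = 1e-6, background = 0) {
  stopifnot(slope > 0, k_floor > 0, background >= 0)
  structure(
    list(slope = slope, intercept = intercept,
         k_floor = k_floor, background = background),
    class = "calibration_params"
  )
}

#' Map aequorin consumption rate to Ca2+ concentration
#'
#' @param k Rate constant(s), s^-1; must be > 0 (the floor is applied
#'   upstream by [rate_constant()]).
#' @param params [calibration_params()].
#' @return Ca2+ concentration(s) in M; strictly increasing in `k`.
#' @examples
#' calibrate_ca(1)      # ~2.76e-6 M
#' calibrate_ca(1e-3)   # ~2.77e-7 M
#' @export
calibrate_ca <- function(k, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("rate constant must be positive and finite", call. = FALSE)
  }
  pca <- params$slope * (-log10(k)) + params$intercept
  10^(-pca)
}

#' Invert the calibration curve: Ca2+ concentration to rate constant
#'
#' Exact algebraic inverse of [calibrate_ca()]; used by the forward
#' simulator to turn a ground-truth Ca2+ trajectory into expected photon
#' emission rates.
#'
#' @param ca Ca2+ concentration(s), M (> 0).
#' @param params [calibration_params()].
#' @return Rate constant(s), s^-1.
#' @export
inverse_calibrate <- function(ca, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(!is.finite(ca)) || any(ca <= 0)) {
    stop("ca must be positive and finite", call. = FALSE)
  }
  pca <- -log10(ca)
  10^(-(pca - params$intercept) / params$slope)
}

#' Remaining aequorin pool as recorded luminescence
#'
#' At each sample the remaining pool is estimated as the tail sum of
#' background-subtracted counts from that sample to the end of the run
#' (discharge included). This denominator inherently corrects for reporter
#' consumption: no further correction is applied.
#'
#' @param trace A `lum_trace` (see [make_luminescence()] / [read_plate()]).
#' @param params [calibration_params()]; only `background` is used.
#' @return Numeric vector, same length as the trace; monotone non-increasing.
#' @export
remaining_pool <- function(trace, params = calibration_params()) {
  stopifnot(inherits(trace, "lum_trace"))
  counts <- pmax(trace$counts - params$background, 0)
  total <- sum(counts)
  if (total <= 0) {
    stop("no luminescence after background subtraction; calibration impossible",
         call. = FALSE)
  }
  rev(cumsum(rev(counts)))
}

#' Per-sample aequorin consumption rate constant
#'
#' k(i) = (counts(i) / integration_window) / remaining(i), computed for
#' samples before the discharge; zero-count samples are floored at
#' `params$k_floor`. k is invariant to a uniform detector-gain rescaling of
#' all counts because it is a ratio of counts to counts.
#'
#' @param trace A `lum_trace` including its discharge phase.
#' @param params [calibration_params()].
#' @return List with `times`, `k` (s^-1) and logical `floored` for the
#'   pre-discharge samples.
#' @export
rate_constant <- function(trace, params = calibration_params()) {
  stopifnot(inherits(trace, "lum_trace"))
  if (is.null(trace$discharge_time) || !is.finite(trace$discharge_time)) {
    stop("trace has no discharge time; calibration impossible", call. = FALSE)
  }
  remaining <- remaining_pool(trace, params)
  pre <- trace$times < trace$discharge_time
  counts <- pmax(trace$counts[pre] - params$background, 0)
  k <- (counts / trace$integration_window) / remaining[pre]
  floored <- counts == 0 | k < params$k_floor
  k[floored] <- params$k_floor
  list(times = trace$times[pre], k = k, floored = floored)
}

#' Calibrate a luminescence trace into a cytosolic Ca2+ trace
#'
#' Composition remaining-pool -> rate-constant -> calibration curve. The
#' output is truncated at the discharge (the discharge samples only serve to
#' close the pool denominator) and records the calibration parameters used.
#'
#' @param trace A `lum_trace` with discharge phase.
#' @param params [calibration_params()].
#' @return A `ca_trace` with `provenance$calibration` set.
#' @export
calibrate_trace <- function(trace, params = calibration_params()) {
  rk <- rate_constant(trace, params)
  ca <- calibrate_ca(rk$k, params)
  out <- new_ca_trace(
    well_id = trace$well_id, times = rk$times, ca = ca,
    provenance = list(calibration = unclass(params),
                      floored = rk$floored,
                      stimulus_time = trace$stimulus_time)
  )
  out
}
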