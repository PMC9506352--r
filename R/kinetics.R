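#' Ground-truth cytosolic Ca2+ kinetics
#'
#' Phenomenological model of a stimulus-evoked cytosolic Ca2+ change in
#' aequorin-expressing seedlings: a double-exponential transient (fast rise,
#' slower decay, normalised so its maximum equals `transient_amplitude`)
#' superimposed on a saturating-exponential sustained elevation, on top of a
#' constant resting baseline. The two terms reproduce the two regimes seen in
#' PAW-challenged plants: transients that dissipate within minutes versus
#' sustained elevations that persist.
#'
#' @param baseline Resting cytosolic Ca2+ concentration (M). Must lie in the
#'   physiological resting range (<= 1e-6 M).
#' @param transient_amplitude Peak height of the transient component above
#'   baseline (M).
#' @param rise_tau Rise time constant of the transient (s).
#' @param decay_tau Decay time constant of the transient (s).
#' @param sustained_amplitude Asymptotic height of the sustained component (M).
#' @param sustained_tau Time constant of the sustained component (s).
#' @param stimulus_time Time of stimulus injection (s from run start).
#' @return An object of class `ca_kinetics`.
#' @examples
#' k <- ca_kinetics(transient_amplitude = 5e-7, rise_tau = 10, decay_tau = 120)
#' tr <- make_ca_trajectory(k, seq(0, 1800, by = 5))
#' @export
ca_kinetics <- function(baseline = 1e-7,
                        transient_amplitude = 0,
                        rise_tau = 10,
                        decay_tau = 120,
                        sustained_amplitude = 0,
                        sustained_tau = 60,
                        stimulus_time = 100) {
  stopifnot(
    is.numeric(baseline), length(baseline) == 1L, baseline >= 0,
    is.numeric(transient_amplitude), transient_amplitude >= 0,
    is.numeric(sustained_amplitude), sustained_amplitude >= 0,
    rise_tau > 0, decay_tau > 0, sustained_tau > 0
  )
  if (baseline > 1e-6) {
    stop("baseline above the resting range (must be <= 1e-6 M)", call. = FALSE)
  }
  structure(
    list(
      baseline = baseline,
      transient_amplitude = transient_amplitude,
      rise_tau = rise_tau,
      decay_tau = decay_tau,
      sustained_amplitude = sustained_amplitude,
      sustained_tau = sustained_tau,
      stimulus_time = stimulus_time
    ),
    class = "ca_kinetics"
  )
}

# Peak time of (exp(-dt/decay) - exp(-dt/rise)) after stimulus; closed form,
# with the rise == decay limit dt* = tau handled analytically.
transient_argmax <- function(rise_tau, decay_tau) {
  if (isTRUE(all.equal(rise_tau, decay_tau))) {
    return(rise_tau)
  }
  log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
}

# Unnormalised transient shape; >= 0 for decay_tau >= rise_tau and for the
# equal-tau limit (dt/tau) * exp(-dt/tau).
transient_shape <- function(dt, rise_tau, decay_tau) {
  if (isTRUE(all.equal(rise_tau, decay_tau))) {
    (dt / rise_tau) * exp(-dt / rise_tau)
  } else {
    exp(-dt / decay_tau) - exp(-dt / rise_tau)
  }
}

#' Evaluate a Ca2+ trajectory on a time grid
#'
#' Before the stimulus the trace equals the baseline exactly; from the
#' stimulus onward the transient and sustained components are added. The
#' transient is rescaled so that its maximum equals `transient_amplitude`.
#'
#' @param kinetics A [ca_kinetics()] object.
#' @param times Strictly increasing time grid (s) starting before the
#'   stimulus.
#' @param well_id Optional well identifier carried on the result.
#' @return A `ca_trace`: list with `well_id`, `times`, `ca` (M) and the
#'   generating kinetics as attribute-like field `kinetics`.
#' @export
make_ca_trajectory <- function(kinetics, times, well_id = "truth") {
  stopifnot(inherits(kinetics, "ca_kinetics"), is.numeric(times))
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1L] >= kinetics$stimulus_time) {
    stop("time grid must start before the stimulus", call. = FALSE)
  }
  dt <- times - kinetics$stimulus_time
  ca <- rep(kinetics$baseline, length(times))
  post <- dt >= 0
  if (any(post)) {
    d <- dt[post]
    norm <- transient_shape(
      transient_argmax(kinetics$rise_tau, kinetics$decay_tau),
      kinetics$rise_tau, kinetics$decay_tau
    )
    transient <- if (kinetics$transient_amplitude > 0) {
      kinetics$transient_amplitude *
        transient_shape(d, kinetics$rise_tau, kinetics$decay_tau) / norm
    } else {
      0
    }
    sustained <- kinetics$sustained_amplitude *
      (1 - exp(-d / kinetics$sustained_tau))
    ca[post] <- kinetics$baseline + transient + sustained
  }
  new_ca_trace(well_id = well_id, times = times, ca = ca,
               provenance = list(kinetics = unclass(kinetics)))
}

#' Closed-form integral of a kinetics model over a post-stimulus window
#'
#' Analytic trapezoid-free integral of the trajectory from the stimulus to
#' `stimulus + window`, including the baseline contribution (the integrated
#' dynamics the assay reports carry no baseline subtraction).
#'
#' @param kinetics A [ca_kinetics()] object.
#' @param window Integration window length (s).
#' @return Integral in M*s.
#' @export
kinetics_auc <- function(kinetics, window) {
  stopifnot(inherits(kinetics, "ca_kinetics"), window > 0)
  k <- kinetics
  base <- k$baseline * window
  trans <- 0
  if (k$transient_amplitude > 0) {
    norm <- transient_shape(transient_argmax(k$rise_tau, k$decay_tau),
                            k$rise_tau, k$decay_tau)
    trans <- if (isTRUE(all.equal(k$rise_tau, k$decay_tau))) {
      tau <- k$rise_tau
      # integral of (t/tau) exp(-t/tau) over [0, W] = tau - (W + tau) exp(-W/tau)
      k$transient_amplitude / norm *
        (tau - (window + tau) * exp(-window / tau))
    } else {
      k$transient_amplitude / norm *
        (k$decay_tau * (1 - exp(-window / k$decay_tau)) -
           k$rise_tau * (1 - exp(-window / k$rise_tau)))
    }
  }
  sust <- k$sustained_amplitude *
    (window - k$sustained_tau * (1 - exp(-window / k$sustained_tau)))
  base + trans + sust
}

new_ca_trace <- function(well_id, times, ca, provenance = list()) {
  structure(
    list(well_id = well_id, times = times, ca = ca, provenance = provenance),
    class = "ca_trace"
  )
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf(
    "<ca_trace> well %s: %d samples, %.0f-%.0f s, Ca %.3g-%.3g M\n",
    x$well_id, length(x$times), min(x$times), max(x$times),
    min(x$ca), max(x$ca)
  ))
  invisible(x)
}

#' @export
print.ca_kinetics <- function(x, ...) {
  cat(sprintf(
    paste0("<ca_kinetics> baseline %.3g M, transient %.3g M ",
           "(rise %g s, decay %g s), sustained %.3g M (tau %g s), ",
           "stimulus %g s\n"),
    x$baseline, x$transient_amplitude, x$rise_tau, x$decay_tau,
    x$sustained_amplitude, x$sustained_tau, x$stimulus_time
  ))
  invisible(x)
}
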