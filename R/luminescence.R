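#' Plate-run acquisition configuration
#'
#' Mirrors the luminometry protocol: each well is visited every
#' `sampling_interval` seconds and photons are integrated over a
#' `integration_window` of 500 ms; the stimulus is injected at 100 s and a
#' discharge solution (1 M CaCl2 / ethanol) is injected near the end of the
#' run to consume the remaining aequorin pool.
#'
#' @param n_wells Number of wells.
#' @param sampling_interval Seconds between successive samples of one well.
#' @param integration_window Photon-integration window per sample (s); must
#'   not exceed the sampling interval.
#' @param stimulus_time Injection time of the treatment (s).
#' @param run_duration Total run length (s).
#' @param discharge_time Injection time of the discharge solution (s);
#'   must satisfy stimulus_time < discharge_time < run_duration.
#' @param seed Integer seed for the photon noise.
#' @return An object of class `plate_run_config`.
#' @export
plate_run_config <- function(n_wells = 1L,
                             sampling_interval = 5,
                             integration_window = 0.5,
                             stimulus_time = 100,
                             run_duration = 2000,
                             discharge_time = 1900,
                             seed = 1L) {
  stopifnot(
    n_wells >= 1L, sampling_interval > 0,
    integration_window > 0, integration_window <= sampling_interval,
    stimulus_time < discharge_time, discharge_time < run_duration
  )
  structure(
    list(n_wells = as.integer(n_wells),
         sampling_interval = sampling_interval,
         integration_window = integration_window,
         stimulus_time = stimulus_time,
         run_duration = run_duration,
         discharge_time = discharge_time,
         seed = as.integer(seed)),
    class = "plate_run_config"
  )
}

new_lum_trace <- function(well_id, times, counts, integration_window,
                          stimulus_time, discharge_time, flags = character()) {
  structure(
    list(well_id = well_id, times = times, counts = counts,
         integration_window = integration_window,
         stimulus_time = stimulus_time, discharge_time = discharge_time,
         flags = flags),
    class = "lum_trace"
  )
}

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf(
    "<lum_trace> well %s: %d samples, %.0f-%.0f s, total %.3g counts%s\n",
    x$well_id, length(x$times), min(x$times), max(x$times), sum(x$counts),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""
  ))
  invisible(x)
}

#' Forward-simulate an aequorin luminescence trace
#'
#' Converts a ground-truth Ca2+ trajectory into Poisson photon counts. At
#' each sample the Ca2+ level sets the aequorin consumption rate k through
#' the inverse calibration curve; the expected recorded counts are the pool
#' consumed during the integration window,
#' `pool * (1 - exp(-k * window))` (= k * pool * window to first order), and
#' the pool is depleted by exactly that factor. The pool is expressed in
#' units of recordable counts, so summed recorded counts conserve the initial
#' pool once the discharge (Ca2+ stepped to `discharge_ca`) has consumed it.
#'
#' @param ca A `ca_trace` covering `[0, run_duration]` (linearly interpolated
#'   at the sampling times).
#' @param pool_counts Initial aequorin pool, in total recordable counts.
#' @param config A [plate_run_config()].
#' @param seed Integer seed; identical seed and inputs reproduce the trace
#'   exactly.
#' @param params [calibration_params()] defining the inverse curve.
#' @param discharge_ca Ca2+ level imposed from the discharge injection on
#'   (default 1e-4 M, saturating).
#' @return A `lum_trace`. If the pool is >99% consumed before the discharge
#'   the trace carries the flag `"pool_exhausted"` (a luminescence floor, not
#'   an error).
#' @export
make_luminescence <- function(ca, pool_counts = 1e7, config = plate_run_config(),
                              seed = config$seed,
                              params = calibration_params(),
                              discharge_ca = 1e-4) {
  stopifnot(inherits(ca, "ca_trace"), inherits(config, "plate_run_config"),
            pool_counts > 0)
  times <- seq(0, config$run_duration, by = config$sampling_interval)
  if (min(ca$times) > 0 || max(ca$times) < config$run_duration) {
    stop("ca trace must cover [0, run_duration]", call. = FALSE)
  }
  ca_t <- stats::approx(ca$times, ca$ca, xout = times, rule = 2)$y
  ca_t[times >= config$discharge_time] <- discharge_ca
  # zero Ca2+ means zero emission rate (the calibration curve itself is only
  # defined for positive concentrations)
  k <- numeric(length(ca_t))
  pos <- ca_t > 0
  k[pos] <- inverse_calibrate(ca_t[pos], params)

  w <- config$integration_window
  n <- length(times)
  mu <- numeric(n)
  pool <- pool_counts
  for (i in seq_len(n)) {
    frac <- -expm1(-k[i] * w)   # fraction of pool consumed this window
    mu[i] <- pool * frac
    pool <- pool * exp(-k[i] * w)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  counts <- stats::rpois(n, mu)

  flags <- character()
  pre <- times < config$discharge_time
  consumed_pre <- sum(mu[pre]) / pool_counts
  if (consumed_pre > 0.99) flags <- c(flags, "pool_exhausted")

  out <- new_lum_trace(
    well_id = ca$well_id, times = times, counts = counts,
    integration_window = w,
    stimulus_time = config$stimulus_time,
    discharge_time = config$discharge_time,
    flags = flags
  )
  # noise-free expectation, kept for model diagnostics (not serialized)
  attr(out, "expected_counts") <- mu
  out
}
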