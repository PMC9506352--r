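#' Analysis epoch within a calcium trace
#'
#' An epoch ties a stimulus (dose) injection to the window over which its
#' signature metrics are computed. In the two-dose protocol each dose gets
#' its own epoch, ending at the next dose or at the end of the trace.
#'
#' @param start Epoch start = stimulus time (s).
#' @param end Analysis window end (s), > start.
#' @param label Identifier, e.g. `"dose1"`.
#' @return An object of class `epoch`.
#' @export
epoch <- function(start, end, label = "dose1") {
  stopifnot(is.numeric(start), is.numeric(end), start < end)
  structure(list(label = label, start = start, end = end), class = "epoch")
}

# samples of a ca_trace inside [from, to); returns index vector
.idx_window <- function(trace, from, to, right_closed = FALSE) {
  if (right_closed) {
    which(trace$times >= from & trace$times <= to)
  } else {
    which(trace$times >= from & trace$times < to)
  }
}

#' Pre-stimulus baseline of an epoch
#'
#' Mean Ca2+ over the 60 s preceding the epoch start; if fewer than 3
#' samples fall in that window, all pre-stimulus samples are used.
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @return Baseline concentration (M).
#' @export
trace_baseline <- function(trace, ep) {
  stopifnot(inherits(trace, "ca_trace"), inherits(ep, "epoch"))
  i <- .idx_window(trace, ep$start - 60, ep$start)
  if (length(i) < 3L) i <- which(trace$times < ep$start)
  if (length(i) == 0L) stop("no pre-stimulus samples", call. = FALSE)
  mean(trace$ca[i])
}

# sd over the same pre-stimulus window (internal; onset threshold)
.baseline_sd <- function(trace, ep) {
  i <- .idx_window(trace, ep$start - 60, ep$start)
  if (length(i) < 3L) i <- which(trace$times < ep$start)
  stats::sd(trace$ca[i])
}

#' Peak Ca2+ within an epoch
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @return List with `peak_ca` (M) and `peak_time` (s); ties broken by the
#'   earliest time.
#' @export
trace_peak <- function(trace, ep) {
  stopifnot(inherits(trace, "ca_trace"), inherits(ep, "epoch"))
  i <- .idx_window(trace, ep$start, ep$end, right_closed = TRUE)
  if (length(i) == 0L) stop("epoch contains no samples", call. = FALSE)
  j <- i[which.max(trace$ca[i])]   # which.max returns the first maximum
  list(peak_ca = trace$ca[j], peak_time = trace$times[j])
}

#' Onset delay of the Ca2+ response
#'
#' Time from the epoch start to the first sample exceeding
#' baseline + `threshold_sd` * (pre-stimulus sd), requiring at least 2
#' consecutive samples above threshold. If the pre-stimulus variance is zero
#' the threshold falls back to 1.05 * baseline (flagged). A trace that never
#' crosses is censored at the window length (flagged), so group statistics
#' stay computable.
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @param threshold_sd Threshold in baseline-sd units (default 3).
#' @return List with `onset_delay` (s), `censored`, `relative_threshold`
#'   flags.
#' @export
onset_delay <- function(trace, ep, threshold_sd = 3) {
  stopifnot(inherits(trace, "ca_trace"), inherits(ep, "epoch"))
  base <- trace_baseline(trace, ep)
  s <- .baseline_sd(trace, ep)
  rel <- FALSE
  if (!is.finite(s) || s <= 0) {
    thr <- base * 1.05
    rel <- TRUE
  } else {
    thr <- base + threshold_sd * s
  }
  # injection happens at ep$start: the response can only appear on samples
  # strictly after it, so a step at the injection registers one interval late
  i <- which(trace$times > ep$start & trace$times <= ep$end)
  above <- trace$ca[i] > thr
  onset_i <- NA_integer_
  if (length(above) >= 2L) {
    two <- which(above[-length(above)] & above[-1L])
    if (length(two)) onset_i <- i[two[1L]]
  }
  if (is.na(onset_i)) {
    return(list(onset_delay = ep$end - ep$start, censored = TRUE,
                relative_threshold = rel, threshold = thr))
  }
  list(onset_delay = trace$times[onset_i] - ep$start, censored = FALSE,
       relative_threshold = rel, threshold = thr)
}

#' Slope of the Ca2+ increase
#'
#' Least-squares slope of Ca2+ versus time from the onset sample to the peak
#' sample. Zero if the peak coincides with (or precedes) the onset.
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @param threshold_sd Onset threshold, passed to [onset_delay()].
#' @return Slope in M/s.
#' @export
rise_slope <- function(trace, ep, threshold_sd = 3) {
  od <- onset_delay(trace, ep, threshold_sd)
  pk <- trace_peak(trace, ep)
  if (od$censored) return(0)
  t_on <- ep$start + od$onset_delay
  i <- which(trace$times >= t_on & trace$times <= pk$peak_time)
  if (length(i) < 2L) return(0)
  unname(stats::coef(stats::lm(trace$ca[i] ~ trace$times[i]))[2L])
}

#' Integrated Ca2+ dynamics over a window
#'
#' Trapezoidal integral of the calibrated Ca2+ values (no baseline
#' subtraction) from the epoch start over `window` seconds (truncated at the
#' epoch end), on the native sampling grid.
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @param window Integration window (s); 1800 (30 min) for single-dose runs,
#'   2700 (45 min) for the two-dose protocol.
#' @return Integral in M*s.
#' @export
integrate_ca <- function(trace, ep, window = 1800) {
  stopifnot(inherits(trace, "ca_trace"), inherits(ep, "epoch"), window > 0)
  to <- min(ep$start + window, ep$end)
  i <- .idx_window(trace, ep$start, to, right_closed = TRUE)
  if (length(i) < 2L) stop("too few samples to integrate", call. = FALSE)
  tt <- trace$times[i]
  y <- trace$ca[i]
  sum(diff(tt) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' All signature metrics for one epoch
#'
#' @param trace A `ca_trace`.
#' @param ep An [epoch()].
#' @param window Integration window (s).
#' @param threshold_sd Onset threshold in baseline-sd units.
#' @return One-row data.frame: `epoch`, `baseline_ca`, `peak_ca`,
#'   `peak_time_s`, `onset_delay_s`, `onset_censored`, `rise_slope`,
#'   `auc`, `window_s`.
#' @export
signature_metrics <- function(trace, ep, window = 1800, threshold_sd = 3) {
  base <- trace_baseline(trace, ep)
  pk <- trace_peak(trace, ep)
  od <- onset_delay(trace, ep, threshold_sd)
  sl <- rise_slope(trace, ep, threshold_sd)
  auc <- integrate_ca(trace, ep, window)
  data.frame(
    well_id = trace$well_id,
    epoch = ep$label,
    baseline_ca = base,
    peak_ca = pk$peak_ca,
    peak_time_s = pk$peak_time,
    onset_delay_s = od$onset_delay,
    onset_censored = od$censored,
    rise_slope = sl,
    auc = auc,
    window_s = window,
    stringsAsFactors = FALSE
  )
}

#' Signature metrics for a multi-dose protocol
#'
#' Builds one epoch per dose injection (each ending at the next injection or
#' at the end of the trace) and computes the full metric set per epoch. The
#' baseline of every epoch after the first is taken from the 60 s preceding
#' its own injection, so consecutive doses are compared on their local
#' pre-stimulus reference.
#'
#' @param trace A `ca_trace`.
#' @param dose_times Increasing injection times (s).
#' @param window Integration window per epoch (s); epochs shorter than the
#'   window are truncated at the next injection (no overlap).
#' @param threshold_sd Onset threshold.
#' @return data.frame with one row per dose epoch.
#' @export
two_dose_analysis <- function(trace, dose_times, window = 2700,
                              threshold_sd = 3) {
  stopifnot(inherits(trace, "ca_trace"), length(dose_times) >= 1L,
            all(diff(dose_times) > 0))
  ends <- c(dose_times[-1L], max(trace$times))
  out <- vector("list", length(dose_times))
  for (i in seq_along(dose_times)) {
    ep <- epoch(dose_times[i], ends[i], label = paste0("dose", i))
    out[[i]] <- signature_metrics(trace, ep, window, threshold_sd)
  }
  do.call(rbind, out)
}
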