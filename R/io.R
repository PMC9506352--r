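#' Write a plate run to the plate CSV dialect
#'
#' The plate file has one row per (well, sample) with columns
#' `well_id,time_s,counts`; the acquisition metadata (sampling interval,
#' integration window, stimulus and discharge times, treatment labels) goes
#' in a JSON sidecar so the CSV stays a plain rectangular table.
#'
#' @param traces List of `lum_trace`.
#' @param path CSV path.
#' @param meta_path JSON sidecar path (default: `path` with `.json`).
#' @param extra Named list merged into the sidecar (e.g. treatment,
#'   dilution).
#' @return Invisibly, the sidecar list.
#' @export
write_plate <- function(traces, path, meta_path = NULL, extra = list()) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1L), "lum_trace")))
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(well_id = tr$well_id, time_s = tr$times, counts = tr$counts,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  t1 <- traces[[1L]]
  meta <- c(list(
    sampling_interval_s = diff(t1$times[1:2]),
    integration_window_s = t1$integration_window,
    stimulus_time_s = t1$stimulus_time,
    discharge_time_s = t1$discharge_time,
    wells = vapply(traces, `[[`, character(1L), "well_id")
  ), extra)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Read a plate run from CSV + JSON sidecar
#'
#' Validates the plate invariants: one row per (well, sample), strictly
#' increasing times per well, non-negative counts, and a discharge time in
#' the sidecar (calibration is impossible without the discharge phase).
#'
#' @param path Plate CSV path.
#' @param meta_path JSON sidecar path (default: `path` with `.json`).
#' @return List of `lum_trace`, one per well, metadata attached.
#' @export
read_plate <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well_id", "time_s", "counts") %in% names(df))) {
    stop("plate CSV must have columns well_id,time_s,counts", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$discharge_time_s) || !is.finite(meta$discharge_time_s)) {
    stop("sidecar missing discharge_time_s; calibration impossible",
         call. = FALSE)
  }
  if (any(df$counts < 0)) stop("negative counts in plate file", call. = FALSE)
  lapply(split(df, df$well_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    if (anyDuplicated(d$time_s)) {
      stop("duplicated (well, time) rows for well ", d$well_id[1L],
           call. = FALSE)
    }
    new_lum_trace(
      well_id = d$well_id[1L], times = d$time_s, counts = d$counts,
      integration_window = meta$integration_window_s,
      stimulus_time = meta$stimulus_time_s,
      discharge_time = meta$discharge_time_s
    )
  })
}

#' Write calibrated Ca2+ traces as CSV
#'
#' Columns `well_id,time_s,ca_molar`; concentrations serialized in molar at
#' full precision.
#'
#' @param traces List of `ca_trace`.
#' @param path CSV path.
#' @export
write_ca_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(well_id = tr$well_id, time_s = tr$times, ca_molar = tr$ca,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calibrated Ca2+ traces from CSV
#'
#' @param path CSV written by [write_ca_traces()].
#' @param stimulus_time Stimulus time to attach to each trace (s).
#' @return List of `ca_trace`.
#' @export
read_ca_traces <- function(path, stimulus_time = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$well_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    new_ca_trace(d$well_id[1L], d$time_s, d$ca_molar,
                 provenance = list(stimulus_time = stimulus_time))
  })
}

#' Write a temperature series as CSV
#'
#' Columns `time_s,temp_C,phase`.
#' @param series A `temperature_series`.
#' @param path CSV path.
#' @export
write_temperature <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_s", "temp_C", "phase")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temperature series from CSV
#'
#' @param path CSV with columns `time_s,temp_C,phase`.
#' @return A `temperature_series` data.frame.
#' @export
read_temperature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "temp_C", "phase") %in% names(df)))
  attr(df, "activation_time") <- max(df$time_s[df$phase == "heating"])
  class(df) <- c("temperature_series", "data.frame")
  df
}
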