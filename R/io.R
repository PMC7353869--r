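# Plain-text interchange: trace / breath-event / trial CSVs and JSON
# configuration. All CSVs are UTF-8 with a header row and '.' decimals.

#' Write / read a sensor trace CSV
#'
#' Columns `t_s, true_flow_ml_s, v_flow, v_press, v_batt`; the fine-grid
#' step is recovered from the time column on read.
#'
#' @param trace A `sensor_trace` data frame.
#' @param path File path.
#' @return `read_trace_csv()` returns a `sensor_trace`;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  utils::write.csv(as.data.frame(trace)[, c("t_s", "true_flow_ml_s",
                                            "v_flow", "v_press", "v_batt")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "true_flow_ml_s", "v_flow", "v_press", "v_batt")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  attr(d, "grid_dt") <- if (nrow(d) > 1) d$t_s[2] - d$t_s[1] else NA_real_
  class(d) <- c("sensor_trace", "data.frame")
  d
}

#' Write / read a breath-event CSV
#'
#' Columns `onset_s, tv_ml, t_insp_s, peak_kpa, interval_s`.
#'
#' @param breaths A `breath_events` data frame from [detect_breaths()].
#' @param path File path.
#' @export
write_breaths_csv <- function(breaths, path) {
  utils::write.csv(as.data.frame(breaths)[, c("onset_s", "tv_ml", "t_insp_s",
                                              "peak_kpa", "interval_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breaths_csv
#' @export
read_breaths_csv <- function(path) {
  d <- utils::read.csv(path)
  class(d) <- c("breath_events", "data.frame")
  d
}

#' Write / read a long-format trial CSV
#'
#' Columns `participant, arm, bv, period, breath_idx, tv_ml, interval_s,
#' tv_class, tv_ok, vi_ok` (see [simulate_trial()]).
#'
#' @param data Trial data frame.
#' @param path File path.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("participant", "arm", "bv", "period", "tv_ok")
  if (!all(need %in% names(d)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read configuration objects from JSON
#'
#' A JSON object whose top-level keys may include `waveform_spec`,
#' `sensor_model`, `device_config` and `thresholds`; each is passed as
#' arguments to the corresponding constructor, so omitted fields take the
#' documented defaults.
#'
#' @param path JSON file path.
#' @return Named list with any of the elements `waveform_spec`,
#'   `sensor_model`, `device_config`, `thresholds`.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(raw$waveform_spec))
    out$waveform_spec <- do.call(waveform_spec, as.list(raw$waveform_spec))
  if (!is.null(raw$sensor_model))
    out$sensor_model <- do.call(sensor_model, as.list(raw$sensor_model))
  if (!is.null(raw$device_config))
    out$device_config <- do.call(device_config, as.list(raw$device_config))
  if (!is.null(raw$thresholds))
    out$thresholds <- do.call(threshold_set, as.list(raw$thresholds))
  out
}

#' Write configuration objects to JSON
#'
#' @param ... Named configuration objects (`waveform_spec`, `sensor_model`,
#'   `device_config`, `thresholds`) created by their constructors.
#' @param path JSON file path.
#' @export
write_config_json <- function(..., path) {
  objs <- list(...)
  objs <- lapply(objs, function(o) unclass(o))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
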