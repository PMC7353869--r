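# Device-controller emulation: ADC sampling/quantisation, voltage-to-flow
# conversion, breath detection with fixed-window tidal-volume accumulation,
# interval timing, display frames and bagging alarms. This path is fully
# deterministic: identical inputs give identical outputs.

#' Device configuration
#'
#' Controller parameters of the feedback device. Defaults mirror the device:
#' 40 Hz sampling (25 ms), 10-bit analogue-to-digital conversion against a
#' 5 V reference, and tidal-volume accumulation over 70 consecutive samples
#' (1.75 s) from breath onset.
#'
#' The breath-onset rule (`onset_flow_threshold`, default 2000 mL/min
#' = 33.3 mL/s, held for `min_onset_samples` consecutive samples) is a
#' documented implementation choice: well below any plausible squeeze peak
#' and above quantisation noise.
#'
#' @param sample_period ADC sampling period (s).
#' @param adc_bits ADC resolution (bits).
#' @param adc_vref ADC reference voltage (V).
#' @param accumulation_samples Number of samples integrated per breath.
#' @param onset_flow_threshold Flow (mL/s) that must be exceeded to open a
#'   breath.
#' @param min_onset_samples Consecutive above-threshold samples required.
#' @param alarm_target_interval Target ventilation interval (s) after which
#'   the bagging alarm fires; default 6 s, the lower edge of the optimal
#'   6--8 s interval.
#' @param full_scale_flow Full-scale flow of the connected sensor (mL/s);
#'   must match the sensor model for faithful reconstruction.
#' @param pressure_range_kpa,pressure_range_v Pressure transfer assumed when
#'   converting the pressure channel back to kPa.
#' @param battery_range_v Voltages mapped linearly to 0 and 100 percent
#'   battery charge.
#' @return An object of class `device_config`.
#' @export
device_config <- function(sample_period = 0.025,
                          adc_bits = 10L,
                          adc_vref = 5,
                          accumulation_samples = 70L,
                          onset_flow_threshold = 2000 / 60,
                          min_onset_samples = 2L,
                          alarm_target_interval = 6,
                          full_scale_flow = 1e5 / 60,
                          pressure_range_kpa = c(0, 10),
                          pressure_range_v = c(0.5, 4.5),
                          battery_range_v = c(3.0, 4.2)) {
  stopifnot(sample_period > 0, adc_bits >= 1, adc_vref > 0,
            accumulation_samples >= 1, onset_flow_threshold > 0,
            min_onset_samples >= 1, alarm_target_interval > 0,
            full_scale_flow > 0)
  structure(list(sample_period = sample_period,
                 adc_bits = as.integer(adc_bits),
                 adc_vref = adc_vref,
                 accumulation_samples = as.integer(accumulation_samples),
                 onset_flow_threshold = onset_flow_threshold,
                 min_onset_samples = as.integer(min_onset_samples),
                 alarm_target_interval = alarm_target_interval,
                 full_scale_flow = full_scale_flow,
                 pressure_range_kpa = as.numeric(pressure_range_kpa),
                 pressure_range_v = as.numeric(pressure_range_v),
                 battery_range_v = as.numeric(battery_range_v)),
            class = "device_config")
}

# floor-to-code quantisation; codes clamped to the ADC range
quantize_voltage <- function(v, bits, vref) {
  n_codes <- 2^bits - 1
  code <- floor(v / vref * n_codes)
  code <- pmin(pmax(code, 0), n_codes)
  list(code = as.integer(code),
       voltage = code / n_codes * vref,
       n_saturated = sum(v < 0 | v > vref))
}

#' Sample and quantize a sensor trace
#'
#' Emulates the ADC front-end: voltages are read at `t = k * sample_period`
#' (nearest fine-grid point) and converted to integer codes by
#' `floor(V / vref * (2^bits - 1))`, clamped to the code range, then mapped
#' back to voltage as `code / (2^bits - 1) * vref`, so the reconstruction
#' error is below one least-significant bit. The flow channel is additionally
#' converted to mL/s via [voltage_to_flow()] and the pressure channel back
#' to kPa.
#'
#' @param trace A `sensor_trace` from [gen_ventilator_trace()] or
#'   [gen_bagvalve_trace()]; its grid must be at least as fine as
#'   `cfg$sample_period`.
#' @param cfg A [device_config()].
#' @return A `device_samples` data frame with columns `t_s`, `v_flow`,
#'   `v_press`, `v_batt` (reconstructed voltages), `flow_ml_s` and
#'   `press_kpa`; attribute `n_saturated` counts out-of-range analogue
#'   samples that were clamped.
#' @export
sample_and_quantize <- function(trace, cfg = device_config()) {
  stopifnot(inherits(trace, "sensor_trace"), inherits(cfg, "device_config"))
  grid_dt <- attr(trace, "grid_dt")
  if (grid_dt > cfg$sample_period + 1e-12)
    stop("trace grid is coarser than the device sampling period")
  empty <- data.frame(t_s = numeric(0), v_flow = numeric(0),
                      v_press = numeric(0), v_batt = numeric(0),
                      flow_ml_s = numeric(0), press_kpa = numeric(0))
  if (nrow(trace) == 0) {
    attr(empty, "sample_period") <- cfg$sample_period
    attr(empty, "n_saturated") <- 0L
    class(empty) <- c("device_samples", "data.frame")
    return(empty)
  }
  t_max <- trace$t_s[nrow(trace)]
  k <- 0:floor(t_max / cfg$sample_period + 1e-9)
  t_k <- k * cfg$sample_period
  idx <- pmin(round(t_k / grid_dt) + 1, nrow(trace))
  qf <- quantize_voltage(trace$v_flow[idx], cfg$adc_bits, cfg$adc_vref)
  qp <- quantize_voltage(trace$v_press[idx], cfg$adc_bits, cfg$adc_vref)
  qb <- quantize_voltage(trace$v_batt[idx], cfg$adc_bits, cfg$adc_vref)
  kr <- cfg$pressure_range_kpa
  vr <- cfg$pressure_range_v
  press <- pmax(kr[1] + (qp$voltage - vr[1]) / diff(vr) * diff(kr), 0)
  out <- data.frame(t_s = t_k,
                    v_flow = qf$voltage,
                    v_press = qp$voltage,
                    v_batt = qb$voltage,
                    flow_ml_s = voltage_to_flow(qf$voltage, cfg),
                    press_kpa = press)
  attr(out, "sample_period") <- cfg$sample_period
  attr(out, "n_saturated") <- qf$n_saturated + qp$n_saturated + qb$n_saturated
  class(out) <- c("device_samples", "data.frame")
  out
}

#' Sensor voltage to flow (device-side transfer)
#'
#' Inverts the mass-flow sensor transfer used by the firmware:
#' `flow = max(0, (Vout - 1)/4) * full_scale_flow`. Readings below the 1 V
#' zero-flow intercept are treated as zero flow, making this a total
#' function.
#'
#' @param vout Sensor output voltage(s), non-negative.
#' @param cfg A [device_config()] supplying `full_scale_flow`.
#' @return Flow in mL/s.
#' @export
voltage_to_flow <- function(vout, cfg = device_config()) {
  if (any(vout < 0)) stop("`vout` must be non-negative")
  pmax(0, (vout - 1) / 4) * cfg$full_scale_flow
}

#' Detect breaths and accumulate tidal volume
#'
#' Runs the controller's breath state machine over quantized samples. A
#' breath opens when flow stays at or above `onset_flow_threshold` for
#' `min_onset_samples` consecutive samples (the onset is the first sample of
#' that run). From onset the device integrates flow over a fixed window of
#' `accumulation_samples` samples (1.75 s by default, truncated at trace
#' end): `tidal_volume = sum(flow_i) * sample_period`. Inspiration time is
#' the time from onset until flow first drops below threshold, capped at the
#' window; peak pressure is the window maximum. No new onset can open inside
#' an active window, so squeezes closer together than the window merge into
#' one detected breath.
#'
#' @param samples A `device_samples` frame from [sample_and_quantize()].
#' @param cfg A [device_config()].
#' @return A `breath_events` data frame: `onset_s`, `tv_ml`, `t_insp_s`,
#'   `peak_kpa`, `interval_s` (onset-to-onset, `NA` for the last breath).
#' @export
detect_breaths <- function(samples, cfg = device_config()) {
  stopifnot(inherits(cfg, "device_config"))
  flow <- samples$flow_ml_s
  press <- samples$press_kpa
  t_s <- samples$t_s
  dt <- cfg$sample_period
  n <- length(flow)
  m <- cfg$min_onset_samples
  w <- cfg$accumulation_samples
  thr <- cfg$onset_flow_threshold
  onset <- integer(0); tv <- numeric(0); tinsp <- numeric(0); pk <- numeric(0)
  i <- 1L
  while (i + m - 1L <= n) {
    if (all(flow[i:(i + m - 1L)] >= thr)) {
      win <- i:min(i + w - 1L, n)
      below <- which(flow[win] < thr)
      onset <- c(onset, i)
      tv <- c(tv, sum(flow[win]) * dt)
      tinsp <- c(tinsp, if (length(below)) (below[1] - 1L) * dt else w * dt)
      pk <- c(pk, max(press[win]))
      i <- i + w
    } else {
      i <- i + 1L
    }
  }
  onset_s <- t_s[onset]
  out <- data.frame(onset_s = onset_s,
                    tv_ml = tv,
                    t_insp_s = tinsp,
                    peak_kpa = pk,
                    interval_s = if (length(onset_s))
                      c(diff(onset_s), NA_real_) else numeric(0))
  class(out) <- c("breath_events", "data.frame")
  out
}

#' Display frames and bagging alarms
#'
#' Replays the device display over a session: one frame per sampling period
#' carrying the last measured tidal volume, seconds since the last breath
#' onset, the countdown to the next recommended bagging
#' (`max(0, alarm_target_interval - elapsed)`), last peak pressure and
#' battery percent. A `bagging_due` alarm fires at most once per
#' inter-breath gap, at the moment the elapsed time since the gap start
#' reaches `alarm_target_interval` (the session start opens the first gap).
#'
#' @param breaths A `breath_events` frame sorted by onset time.
#' @param cfg A [device_config()].
#' @param duration Session length to replay (s).
#' @param battery_voltage Battery voltage assumed for the battery gauge (V).
#' @return A list with elements `frames` (data frame of display fields) and
#'   `alarms` (data frame `t_s`, `kind`).
#' @export
run_display <- function(breaths, cfg = device_config(), duration,
                        battery_voltage = 3.7) {
  stopifnot(inherits(cfg, "device_config"), duration >= 0)
  onsets <- breaths$onset_s
  if (is.unsorted(onsets)) stop("`breaths` must be sorted by onset time")
  t <- (0:floor(duration / cfg$sample_period + 1e-9)) * cfg$sample_period
  last_idx <- findInterval(t + 1e-12, onsets)
  since <- ifelse(last_idx > 0, t - onsets[last_idx], t)
  batt <- battery_percent(battery_voltage, cfg)
  frames <- data.frame(
    t_s = t,
    last_tv_ml = ifelse(last_idx > 0, breaths$tv_ml[last_idx], NA_real_),
    seconds_since_last_breath = since,
    countdown_to_next_bagging = pmax(0, cfg$alarm_target_interval - since),
    peak_kpa = ifelse(last_idx > 0, breaths$peak_kpa[last_idx], NA_real_),
    battery_percent = batt)
  gap_start <- c(0, onsets)
  gap_end <- c(onsets, duration)
  due <- gap_start + cfg$alarm_target_interval
  fire <- due <= gap_end + 1e-9
  alarms <- data.frame(t_s = due[fire],
                       kind = rep("bagging_due", sum(fire)))
  list(frames = frames, alarms = alarms)
}

# battery gauge: linear between the configured empty/full voltages
battery_percent <- function(v, cfg = device_config()) {
  r <- cfg$battery_range_v
  pmin(pmax((v - r[1]) / (r[2] - r[1]) * 100, 0), 100)
}

#' Run the full device pipeline on a sensor trace
#'
#' Convenience wrapper: [sample_and_quantize()] then [detect_breaths()].
#'
#' @inheritParams sample_and_quantize
#' @return A `breath_events` data frame.
#' @export
emulate_device <- function(trace, cfg = device_config()) {
  detect_breaths(sample_and_quantize(trace, cfg), cfg)
}
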