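# Synthetic flow/pressure waveforms and the flow-sensor voltage transfer.
# Units throughout: volume mL, flow mL/s, time s, voltage V, pressure kPa.

#' Waveform specification
#'
#' Describes a synthetic ventilation waveform: either a volume-controlled
#' mechanical-ventilator trace (constant inspiratory flow, zero expiratory
#' flow) or a sequence of human bag-valve squeezes with operator variability.
#'
#' In `"ventilator"` mode the cycle is defined by `resp_rate` and `ie_ratio`:
#' the cycle length is `60/resp_rate` seconds and the inspiratory fraction is
#' `i/(i+e)`. In `"bagvalve"` mode per-squeeze tidal volumes are drawn from a
#' normal distribution truncated to `(0, bv_max]` (1300 mL for adult bags,
#' 300 mL for paediatric bags) and onset-to-onset intervals from a normal
#' truncated below at the squeeze duration.
#'
#' @param mode `"ventilator"` or `"bagvalve"`.
#' @param set_tv Set tidal volume per breath (mL, ventilator mode).
#' @param resp_rate Respiration rate (breaths/min, ventilator mode).
#' @param ie_ratio Length-2 numeric, inspiration:expiration ratio (default 1:5).
#' @param duration Trace duration (s).
#' @param squeeze_profile Flow shape of a bag squeeze: `"half_sine"` (smooth
#'   onset/offset, the default) or `"rectangular"` (constant flow, convenient
#'   for analytic checks).
#' @param squeeze_time Duration of one squeeze (s, bagvalve mode).
#' @param operator_tv_mean,operator_tv_sd Mean and SD (mL) of the operator's
#'   delivered squeeze volume.
#' @param operator_interval_mean,operator_interval_sd Mean and SD (s) of the
#'   operator's onset-to-onset squeeze interval.
#' @param bv_type `"adult"` or `"paediatric"`; sets the maximum deliverable
#'   squeeze volume (1300 / 300 mL).
#' @param seed Integer seed making the generated trace reproducible, or
#'   `NULL` to use the current RNG state.
#' @return An object of class `waveform_spec`.
#' @seealso [gen_ventilator_trace()], [gen_bagvalve_trace()]
#' @export
waveform_spec <- function(mode = c("ventilator", "bagvalve"),
                          set_tv = 450,
                          resp_rate = 10,
                          ie_ratio = c(1, 5),
                          duration = 120,
                          squeeze_profile = c("half_sine", "rectangular"),
                          squeeze_time = 1,
                          operator_tv_mean = 450,
                          operator_tv_sd = 0,
                          operator_interval_mean = 6,
                          operator_interval_sd = 0,
                          bv_type = c("adult", "paediatric"),
                          seed = NULL) {
  mode <- match.arg(mode)
  squeeze_profile <- match.arg(squeeze_profile)
  bv_type <- match.arg(bv_type)
  stopifnot(resp_rate > 0, duration >= 0,
            length(ie_ratio) == 2, all(ie_ratio > 0),
            squeeze_time > 0)
  if (mode == "ventilator" && set_tv <= 0)
    stop("`set_tv` must be positive in ventilator mode")
  if (mode == "bagvalve") {
    if (operator_tv_sd < 0 || operator_interval_sd < 0)
      stop("operator SDs must be non-negative")
    if (operator_tv_mean <= 0)
      stop("`operator_tv_mean` must be positive")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(mode = mode, set_tv = set_tv, resp_rate = resp_rate,
                 ie_ratio = as.numeric(ie_ratio), duration = duration,
                 squeeze_profile = squeeze_profile,
                 squeeze_time = squeeze_time,
                 operator_tv_mean = operator_tv_mean,
                 operator_tv_sd = operator_tv_sd,
                 operator_interval_mean = operator_interval_mean,
                 operator_interval_sd = operator_interval_sd,
                 bv_type = bv_type, seed = seed),
            class = "waveform_spec")
}

#' Flow/pressure sensor model
#'
#' Parameters of the analogue sensing front-end: the mass-flow sensor's
#' full-scale flow (mapping linearly to its 1--5 V output), the pressure
#' sensor's kPa-to-volt map, additive Gaussian voltage noise per channel,
#' and the battery voltage reported on the third analogue channel.
#'
#' The full-scale flow is a required configuration value; the default,
#' 100 000 mL/min (about 1667 mL/s), keeps a 1-second 550 mL delivery well
#' inside range. The pressure default maps 0--10 kPa to 0.5--4.5 V.
#'
#' @param full_scale_flow Sensor full-scale flow (mL/s).
#' @param pressure_range_kpa,pressure_range_v Length-2 vectors defining the
#'   linear pressure transfer (kPa endpoints and the voltages they map to).
#' @param noise_sd_flow,noise_sd_pressure Additive Gaussian noise SD (V) on
#'   the flow / pressure channels. Zero gives noise-free traces.
#' @param battery_voltage Battery voltage placed on the battery channel (V).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(full_scale_flow = 1e5 / 60,
                         pressure_range_kpa = c(0, 10),
                         pressure_range_v = c(0.5, 4.5),
                         noise_sd_flow = 0,
                         noise_sd_pressure = 0,
                         battery_voltage = 3.7) {
  stopifnot(full_scale_flow > 0, noise_sd_flow >= 0, noise_sd_pressure >= 0,
            length(pressure_range_kpa) == 2, length(pressure_range_v) == 2,
            diff(pressure_range_kpa) > 0, diff(pressure_range_v) > 0)
  structure(list(full_scale_flow = full_scale_flow,
                 pressure_range_kpa = as.numeric(pressure_range_kpa),
                 pressure_range_v = as.numeric(pressure_range_v),
                 noise_sd_flow = noise_sd_flow,
                 noise_sd_pressure = noise_sd_pressure,
                 battery_voltage = battery_voltage),
            class = "sensor_model")
}

#' Flow to sensor output voltage
#'
#' The mass-flow sensor's transfer: `Vout = 1 V + 4 V * flow / full_scale`,
#' i.e. zero flow reads 1 V and full-scale flow reads 5 V. Flows above full
#' scale saturate at 5 V (a warning reports how many samples clipped).
#'
#' @param flow Flow (mL/s), non-negative; vectorised.
#' @param model A [sensor_model()].
#' @return Output voltage(s) in `[1, 5]` V.
#' @seealso [voltage_to_flow()] for the inverse used by the device firmware.
#' @export
flow_to_voltage <- function(flow, model = sensor_model()) {
  if (any(flow < 0)) stop("`flow` must be non-negative")
  n_sat <- sum(flow > model$full_scale_flow)
  if (n_sat > 0)
    warning(sprintf("%d flow sample(s) above full scale; saturated at 5 V",
                    n_sat))
  1 + 4 * pmin(flow, model$full_scale_flow) / model$full_scale_flow
}

# linear pressure transfer (kPa -> V), clamped to the stated voltage range
pressure_to_voltage <- function(p_kpa, model) {
  k <- model$pressure_range_kpa
  v <- model$pressure_range_v
  out <- v[1] + (p_kpa - k[1]) / (k[2] - k[1]) * (v[2] - v[1])
  pmin(pmax(out, v[1]), v[2])
}

# Draw from a normal truncated to [lower, upper] by inverse-CDF.
# sd = 0 degenerates to the (clamped) mean.
rtrunc_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) stop("truncation interval has no probability mass")
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Assemble the sensor_trace data frame from a fine-grid flow vector.
build_trace <- function(t, flow, model, grid_dt, noisy = TRUE) {
  v_true <- flow_to_voltage(flow, model)
  # crude airway-pressure surrogate: linear in flow, top of the pressure
  # range at full-scale flow (display plumbing, not lung mechanics)
  p_kpa <- model$pressure_range_kpa[2] * flow / model$full_scale_flow
  v_press <- pressure_to_voltage(p_kpa, model)
  if (noisy && model$noise_sd_flow > 0)
    v_flow <- v_true + stats::rnorm(length(v_true), 0, model$noise_sd_flow)
  else v_flow <- v_true
  if (noisy && model$noise_sd_pressure > 0)
    v_press <- v_press + stats::rnorm(length(v_press), 0,
                                      model$noise_sd_pressure)
  out <- data.frame(t_s = t,
                    true_flow_ml_s = flow,
                    v_flow = v_flow,
                    v_press = v_press,
                    v_batt = rep(model$battery_voltage, length(t)))
  attr(out, "grid_dt") <- grid_dt
  class(out) <- c("sensor_trace", "data.frame")
  out
}

#' Generate a volume-controlled ventilator trace
#'
#' Constant inspiratory flow of `set_tv / T_insp` for the inspiratory part of
#' each cycle and zero flow during expiration, where
#' `T_insp = (60/resp_rate) * i/(i+e)`. Breath onsets are spaced exactly
#' `60/resp_rate` s apart and each breath integrates to `set_tv` up to grid
#' discretisation.
#'
#' @param spec A [waveform_spec()] with `mode = "ventilator"`.
#' @param model A [sensor_model()]; its noise SDs add Gaussian noise to the
#'   voltage channels (the `true_flow_ml_s` column always remains noise-free
#'   ground truth).
#' @param grid_dt Simulation grid step (s). The default 1 ms is much finer
#'   than the device's 25 ms sampling so firmware sampling is a genuine
#'   down-sampling of the analogue truth.
#' @return A `sensor_trace` data frame with columns `t_s`, `true_flow_ml_s`,
#'   `v_flow`, `v_press`, `v_batt` and attribute `grid_dt`.
#' @examples
#' sp <- waveform_spec("ventilator", set_tv = 350, duration = 12)
#' tr <- gen_ventilator_trace(sp)
#' sum(tr$true_flow_ml_s) * attr(tr, "grid_dt") / 2  # ~350 mL per breath
#' @export
gen_ventilator_trace <- function(spec, model = sensor_model(),
                                 grid_dt = 0.001) {
  stopifnot(inherits(spec, "waveform_spec"), grid_dt > 0)
  if (spec$mode != "ventilator")
    stop("`spec$mode` must be \"ventilator\"")
  t_cycle <- 60 / spec$resp_rate
  t_insp <- t_cycle * spec$ie_ratio[1] / sum(spec$ie_ratio)
  if (t_insp < 2 * grid_dt)
    stop("inspiration time shorter than two grid steps; pulse unresolvable")
  n <- floor(spec$duration / grid_dt + 1e-9)
  if (n == 0)
    return(build_trace(numeric(0), numeric(0), model, grid_dt))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_cycle <- round(t_cycle / grid_dt)
  n_insp <- round(t_insp / grid_dt)
  flow_insp <- spec$set_tv / (n_insp * grid_dt)
  pattern <- rep(c(flow_insp, 0), c(n_insp, n_cycle - n_insp))
  flow <- rep_len(pattern, n)
  t <- (seq_len(n) - 1) * grid_dt
  build_trace(t, flow, model, grid_dt)
}

#' Generate a bag-valve squeeze trace with operator variability
#'
#' Emulates a human operator squeezing a self-inflating bag: squeeze volumes
#' are drawn from a truncated normal on `(0, bv_max]` (1300 mL adult, 300 mL
#' paediatric) and onset-to-onset intervals from a normal truncated below at
#' the squeeze duration. Each squeeze delivers its drawn volume over
#' `squeeze_time` seconds with the configured flow profile.
#'
#' @inheritParams gen_ventilator_trace
#' @param spec A [waveform_spec()] with `mode = "bagvalve"`; the trace is
#'   reproducible given `spec$seed`.
#' @return A `sensor_trace` data frame (see [gen_ventilator_trace()]); the
#'   drawn per-squeeze volumes and onsets are attached as attributes
#'   `squeeze_volumes` and `squeeze_onsets`.
#' @export
gen_bagvalve_trace <- function(spec, model = sensor_model(),
                               grid_dt = 0.001) {
  stopifnot(inherits(spec, "waveform_spec"), grid_dt > 0)
  if (spec$mode != "bagvalve")
    stop("`spec$mode` must be \"bagvalve\"")
  if (spec$operator_interval_mean <= spec$squeeze_time)
    stop("`operator_interval_mean` must exceed the squeeze duration")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  bv_max <- bag_max_volume(spec$bv_type)
  n <- floor(spec$duration / grid_dt + 1e-9)
  flow <- numeric(n)
  t <- (seq_len(n) - 1) * grid_dt
  n_sq <- max(1L, round(spec$squeeze_time / grid_dt))
  shape <- switch(spec$squeeze_profile,
                  rectangular = rep(1, n_sq),
                  half_sine = sin(pi * (seq_len(n_sq) - 0.5) / n_sq))
  shape <- shape / (sum(shape) * grid_dt)  # unit-volume squeeze kernel
  onsets <- numeric(0)
  volumes <- numeric(0)
  onset <- 0
  while (onset + spec$squeeze_time <= spec$duration + 1e-9 && n > 0) {
    vol <- rtrunc_normal(1, spec$operator_tv_mean, spec$operator_tv_sd,
                         lower = 0, upper = bv_max)
    i0 <- round(onset / grid_dt)
    idx <- i0 + seq_len(n_sq)
    idx <- idx[idx <= n]
    flow[idx] <- flow[idx] + vol * shape[seq_along(idx)]
    onsets <- c(onsets, onset)
    volumes <- c(volumes, vol)
    gap <- rtrunc_normal(1, spec$operator_interval_mean,
                         spec$operator_interval_sd,
                         lower = spec$squeeze_time)
    onset <- onset + gap
  }
  out <- build_trace(t, flow, model, grid_dt)
  attr(out, "squeeze_onsets") <- onsets
  attr(out, "squeeze_volumes") <- volumes
  out
}

# Maximum deliverable bag volume by bag size.
bag_max_volume <- function(bv_type) {
  switch(match.arg(bv_type, c("adult", "paediatric")),
         adult = 1300, paediatric = 300)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %d samples, grid %.4g ms, span %.2f s\n",
              nrow(x), 1000 * attr(x, "grid_dt"),
              if (nrow(x)) max(x$t_s) else 0))
  if (nrow(x)) utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
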