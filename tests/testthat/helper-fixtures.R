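# Shared fixtures, built in code.

# noise-free sensor/config pair used across firmware tests
nf_model <- function(...) sensor_model(noise_sd_flow = 0, ...)

vent_spec <- function(tv, duration = 120, rr = 10) {
  waveform_spec("ventilator", set_tv = tv, resp_rate = rr,
                ie_ratio = c(1, 5), duration = duration)
}

# rectangular single squeezes at given onsets/volumes over a fine grid;
# exercises detect_breaths with an analytically known input
rect_trace <- function(onsets, volumes, squeeze_time = 1, duration = 10,
                       model = nf_model(), grid_dt = 0.001) {
  n <- round(duration / grid_dt)
  flow <- numeric(n)
  for (k in seq_along(onsets)) {
    i0 <- round(onsets[k] / grid_dt)
    idx <- i0 + seq_len(round(squeeze_time / grid_dt))
    idx <- idx[idx <= n]
    flow[idx] <- flow[idx] + volumes[k] / squeeze_time
  }
  tr <- data.frame(t_s = (seq_len(n) - 1) * grid_dt,
                   true_flow_ml_s = flow,
                   v_flow = flow_to_voltage(flow, model),
                   v_press = 0.5,
                   v_batt = 3.7)
  attr(tr, "grid_dt") <- grid_dt
  class(tr) <- c("sensor_trace", "data.frame")
  tr
}

# published trial adequacy results used as fixture inputs: adequacy category counts
# per bag type and arm, and the interval denominators of each cell
published_adequacy_counts <- function() {
  list(
    adult = list(RAV = c(optimal = 262, hypo = 220, hyper = 72),
                 NV = c(optimal = 98, hypo = 309, hyper = 124)),
    paediatric = list(RAV = c(optimal = 495, hypo = 53, hyper = 5),
                      NV = c(optimal = 380, hypo = 131, hyper = 12)),
    vi = list(adult = list(RAV = c(optimal = 505, total = 528),
                           NV = c(optimal = 254, total = 506)),
              paediatric = list(RAV = c(optimal = 506, total = 528),
                                NV = c(optimal = 284, total = 497))))
}

# one-sided analytic bound on firmware TV error for a noise-free
# rectangular pulse: quantisation (1 LSB over the window) + one sample of
# peak flow at the pulse edges
fw_tv_bound <- function(cfg, peak_flow) {
  lsb_flow <- cfg$adc_vref / (2^cfg$adc_bits - 1) / 4 * cfg$full_scale_flow
  lsb_flow * cfg$accumulation_samples * cfg$sample_period +
    cfg$sample_period * peak_flow
}
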