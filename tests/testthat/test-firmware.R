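test_that("quantisation maps anchor voltages to the right codes", {
  q <- ventfeedback:::quantize_voltage(c(0, 5), 10, 5)
  expect_equal(q$code, c(0L, 1023L))
  expect_equal(q$voltage, c(0, 5))
  # reconstruction error below one LSB over a dense voltage sweep
  # (brute force across every code bin)
  v <- seq(0, 5, length.out = 4096)
  q2 <- ventfeedback:::quantize_voltage(v, 10, 5)
  expect_true(all(abs(q2$voltage - v) <= 5 / 1023 + 1e-12))
  expect_true(all(diff(q2$code) >= 0))
  # a constant 3.000 V line reconstructs within the step bound
  expect_lt(abs(ventfeedback:::quantize_voltage(3, 10, 5)$voltage - 3),
            5 / 2^10)
})

test_that("device-side voltage-to-flow clamps below the intercept", {
  cfg <- device_config()
  expect_equal(voltage_to_flow(1, cfg), 0)
  expect_equal(voltage_to_flow(5, cfg), cfg$full_scale_flow)
  expect_equal(voltage_to_flow(0.8, cfg), 0)
  expect_error(voltage_to_flow(-0.1, cfg), "non-negative")
})

test_that("sampling picks the device grid and flags saturation", {
  tr <- gen_ventilator_trace(vent_spec(350, duration = 12), nf_model())
  cfg <- device_config()
  s <- sample_and_quantize(tr, cfg)
  expect_equal(s$t_s, (0:479) * 0.025)
  expect_equal(attr(s, "n_saturated"), 0L)
  # coarse trace rejected
  tr2 <- tr; attr(tr2, "grid_dt") <- 0.05
  expect_error(sample_and_quantize(tr2, cfg), "coarser")
})

test_that("breath detection recovers ventilator volumes and intervals", {
  cfg <- device_config()
  for (tv in c(150, 350, 550)) {
    tr <- gen_ventilator_trace(vent_spec(tv), nf_model())
    br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
    expect_equal(nrow(br), 20)
    expect_equal(br$interval_s[-20], rep(6, 19))
    expect_true(is.na(br$interval_s[20]))
    bound <- fw_tv_bound(cfg, tv)  # quantisation + edge-sample bound
    expect_true(all(abs(br$tv_ml - tv) <= bound))
    # with the default config the relative error is under 2 %
    expect_true(all(abs(br$tv_ml - tv) / tv < 0.02))
    expect_true(all(br$t_insp_s <= cfg$accumulation_samples * cfg$sample_period))
  }
})

test_that("no flow means no breaths, and empty input is tolerated", {
  cfg <- device_config()
  tr <- rect_trace(onsets = numeric(0), volumes = numeric(0), duration = 5)
  br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
  expect_equal(nrow(br), 0)
  tr0 <- gen_ventilator_trace(vent_spec(350, duration = 0), nf_model())
  expect_equal(nrow(detect_breaths(sample_and_quantize(tr0, cfg), cfg)), 0)
})

test_that("squeezes closer than the accumulation window merge", {
  cfg <- device_config()
  tr <- rect_trace(onsets = c(1, 2), volumes = c(300, 300),
                   squeeze_time = 0.5, duration = 8)
  br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
  # second onset at +1.0 s falls inside the 1.75 s window: one event
  # integrating both squeezes
  expect_equal(nrow(br), 1)
  expect_equal(br$tv_ml, 600, tolerance = fw_tv_bound(cfg, 600))
  # spaced beyond the window they are two events
  tr2 <- rect_trace(onsets = c(1, 4), volumes = c(300, 300),
                    squeeze_time = 0.5, duration = 8)
  br2 <- detect_breaths(sample_and_quantize(tr2, cfg), cfg)
  expect_equal(nrow(br2), 2)
  expect_equal(br2$interval_s[1], 3)
})

test_that("detected volume scales linearly with true flow", {
  cfg <- device_config()
  base <- 500
  for (c_scale in c(0.25, 0.5, 1)) {
    tr <- rect_trace(onsets = 1, volumes = base * c_scale, duration = 6)
    br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
    expect_equal(nrow(br), 1)
    expect_equal(br$tv_ml, base * c_scale,
                 tolerance = fw_tv_bound(cfg, base * c_scale))
  }
})

test_that("firmware path is deterministic", {
  tr <- gen_ventilator_trace(vent_spec(450, duration = 24), nf_model())
  cfg <- device_config()
  expect_identical(detect_breaths(sample_and_quantize(tr, cfg), cfg),
                   detect_breaths(sample_and_quantize(tr, cfg), cfg))
})

test_that("display frames count down and alarms fire once per gap", {
  cfg <- device_config()  # alarm target 6 s
  br <- data.frame(onset_s = seq(0, 114, by = 6), tv_ml = 450,
                   t_insp_s = 1, peak_kpa = 2,
                   interval_s = c(rep(6, 19), NA))
  out <- run_display(br, cfg, duration = 120)
  # one alarm per 6 s gap, at gap start + 6 s
  expect_equal(out$alarms$t_s, seq(6, 120, by = 6))
  expect_true(all(out$alarms$kind == "bagging_due"))
  # countdown invariant
  with(out$frames, expect_equal(
    countdown_to_next_bagging,
    pmax(0, cfg$alarm_target_interval - seconds_since_last_breath)))

  # no breaths at all: single alarm referenced to session start
  out2 <- run_display(br[0, ], cfg, duration = 10)
  expect_equal(out2$alarms$t_s, 6)
  # breaths faster than the target never alarm
  br3 <- data.frame(onset_s = seq(0, 25, by = 5), tv_ml = 450, t_insp_s = 1,
                    peak_kpa = 2, interval_s = c(rep(5, 5), NA))
  expect_equal(nrow(run_display(br3, cfg, duration = 30)$alarms), 0)
})

test_that("battery gauge is linear and clamped", {
  cfg <- device_config()
  expect_equal(ventfeedback:::battery_percent(3.0, cfg), 0)
  expect_equal(ventfeedback:::battery_percent(4.2, cfg), 100)
  expect_equal(ventfeedback:::battery_percent(3.6, cfg), 50)
  expect_equal(ventfeedback:::battery_percent(5.0, cfg), 100)
})
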