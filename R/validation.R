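# Bench-validation protocol: known-volume ventilator deliveries through the
# device emulator, difference ratios, per-level statistics and tolerance
# bands.

#' Difference ratio between device and reference tidal volume
#'
#' `(device_tv - reference_tv) / reference_tv`: the relative error of the
#' device reading against the reference analyser.
#'
#' @param device_tv Device-measured tidal volume (mL); vectorised.
#' @param reference_tv Reference tidal volume (mL), strictly positive.
#' @return Dimensionless difference ratio(s).
#' @examples
#' difference_ratio(144.0, 149.4)  # -0.0361...
#' @export
difference_ratio <- function(device_tv, reference_tv) {
  if (any(reference_tv <= 0)) stop("`reference_tv` must be positive")
  (device_tv - reference_tv) / reference_tv
}

#' Compare two sample means
#'
#' Two-sided Welch (unequal-variance) t-test, with a paired option. When
#' both samples are (numerically) constant the t statistic is undefined;
#' the convention here is p = 1 for equal means and p = 0 otherwise.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2 (equal
#'   lengths when `paired`).
#' @param paired Use a paired t-test instead of Welch.
#' @return The two-sided p-value.
#' @export
mean_comparison <- function(sample_a, sample_b, paired = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  eps <- .Machine$double.eps^0.5
  degenerate <- if (paired) {
    stats::sd(sample_a - sample_b) < eps
  } else {
    stats::sd(sample_a) < eps && stats::sd(sample_b) < eps
  }
  if (degenerate) {
    return(if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) 1 else 0)
  }
  stats::t.test(sample_a, sample_b, paired = paired,
                var.equal = FALSE)$p.value
}

#' Run the device validation protocol
#'
#' For each set tidal volume, generates `reps` single-breath
#' volume-controlled ventilator deliveries (I:E 1:5, rate 10/min), adds
#' Gaussian voltage noise on the flow channel as a hardware-noise surrogate,
#' runs the device emulator, and records the device reading against the
#' reference (the exact integral of the noise-free flow). Reports per-level
#' mean/SD for both, a per-level mean-comparison p-value, and the
#' proportions of difference ratios within +/-5 % and +/-10 %.
#'
#' Reps in which noise spikes fabricate extra onsets use the first detected
#' breath; reps with no detected breath are recorded as missing, never
#' silently dropped.
#'
#' @param cfg A [device_config()].
#' @param model A [sensor_model()]; its `noise_sd_flow` is overridden by
#'   `noise_sd`.
#' @param levels Set tidal volumes (mL).
#' @param reps Deliveries per level (>= 2).
#' @param noise_sd Flow-channel voltage noise SD (V). The default 0.1 V
#'   yields per-level device SDs of a few mL, the same order as a real
#'   bench run; it is a surrogate, not a sensor model. Zero gives a fully
#'   deterministic report.
#' @param paired Use a paired per-level mean comparison.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `validation_report`: `per_rep` (level, rep,
#'   reference_tv, device_tv, diff_ratio), `per_level` (means, SDs,
#'   p-values, missing counts), `bands` (counts and proportions within
#'   +/-5 % and +/-10 %), `n_measurements`, `n_missing`.
#' @export
run_validation <- function(cfg = device_config(), model = sensor_model(),
                           levels = c(150, 250, 350, 450, 550),
                           reps = 25, noise_sd = 0.1, paired = FALSE,
                           seed = NULL) {
  stopifnot(reps >= 2, all(levels > 0), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  model$noise_sd_flow <- noise_sd
  t_cycle <- 6  # rate 10/min
  rows <- vector("list", length(levels) * reps)
  k <- 0L
  for (lv in levels) {
    sp <- waveform_spec("ventilator", set_tv = lv, resp_rate = 10,
                        ie_ratio = c(1, 5), duration = t_cycle)
    for (r in seq_len(reps)) {
      tr <- gen_ventilator_trace(sp, model)
      ref <- sum(tr$true_flow_ml_s) * attr(tr, "grid_dt")
      br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
      dev <- if (nrow(br) >= 1) br$tv_ml[1] else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(level = lv, rep = r, reference_tv = ref,
                              device_tv = dev,
                              diff_ratio = if (is.na(dev)) NA_real_
                                           else difference_ratio(dev, ref))
    }
  }
  per_rep <- do.call(rbind, rows)
  per_level <- do.call(rbind, lapply(levels, function(lv) {
    d <- per_rep[per_rep$level == lv, ]
    ok <- !is.na(d$device_tv)
    p <- if (sum(ok) >= 2)
      mean_comparison(d$reference_tv[ok], d$device_tv[ok], paired = paired)
    else NA_real_
    data.frame(level = lv, n = nrow(d), n_missing = sum(!ok),
               ref_mean = mean(d$reference_tv), ref_sd = stats::sd(d$reference_tv),
               dev_mean = mean(d$device_tv[ok]), dev_sd = stats::sd(d$device_tv[ok]),
               p_value = p)
  }))
  bands <- tolerance_bands(per_rep$diff_ratio)
  structure(list(per_rep = per_rep, per_level = per_level, bands = bands,
                 n_measurements = nrow(per_rep),
                 n_missing = sum(is.na(per_rep$device_tv)),
                 noise_sd = noise_sd),
            class = "validation_report")
}

#' Tolerance-band counts of difference ratios
#'
#' How many difference ratios fall within +/-5 % and +/-10 % (bounds
#' inclusive). `NA` ratios (failed detections) are excluded from the
#' denominator.
#'
#' @param diff_ratios Numeric vector of dimensionless difference ratios.
#' @return List with `n`, `within_5`, `within_10`, `prop_5`, `prop_10`.
#' @examples
#' tolerance_bands(c(-0.04, 0.06, 0.09, 0.12))  # 1 within 5%, 3 within 10%
#' @export
tolerance_bands <- function(diff_ratios) {
  dr <- diff_ratios[!is.na(diff_ratios)]
  list(n = length(dr),
       within_5 = sum(abs(dr) <= 0.05),
       within_10 = sum(abs(dr) <= 0.10),
       prop_5 = if (length(dr)) mean(abs(dr) <= 0.05) else NA_real_,
       prop_10 = if (length(dr)) mean(abs(dr) <= 0.10) else NA_real_)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d measurements (%d missing), noise sd %.3g V\n",
              x$n_measurements, x$n_missing, x$noise_sd))
  print(format(x$per_level, digits = 4), row.names = FALSE)
  cat(sprintf("within +/-5%%: %d/%d (%.1f%%);  within +/-10%%: %d/%d (%.1f%%)\n",
              x$bands$within_5, x$bands$n, 100 * x$bands$prop_5,
              x$bands$within_10, x$bands$n, 100 * x$bands$prop_10))
  invisible(x)
}

#' Validation report as a data frame
#'
#' One row per level, mirroring the bench-report layout, with band
#' proportions attached as attributes.
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  out <- x$per_level
  attr(out, "prop_within_5") <- x$bands$prop_5
  attr(out, "prop_within_10") <- x$bands$prop_10
  out
}
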