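# Crossover-trial assembly and analysis: adequacy proportion tables,
# chi-square comparisons, crude odds ratios, the spec'd marginal-model
# wrapper, McNemar sample size, and end-to-end trial simulation.

#' Category percentages from counts
#'
#' Percentages `100 * count / sum(counts)` reported to two decimals, the
#' arithmetic behind an "N (%)" results table.
#'
#' @param counts Non-negative numeric vector (optionally named).
#' @return Named numeric vector of percentages rounded to 2 decimals.
#' @examples
#' proportions_from_counts(c(optimal = 262, hypo = 220, hyper = 72))
#' @export
proportions_from_counts <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  round(100 * counts / sum(counts), 2)
}

#' Adequacy proportions by arm and bag type
#'
#' Per (bag type x arm) cell: number of ventilations, tidal-volume class
#' counts and percentages (hypo/optimal/hyper), and interval class counts
#' and percentages over the non-missing intervals (the last breath of each
#' session has none).
#'
#' @param data A long-format trial data frame as produced by
#'   [simulate_trial()]: columns `arm`, `bv`, `tv_class`, `vi_ok`.
#' @return Data frame with one row per `bv` x `arm` combination.
#' @export
proportions_table <- function(data) {
  stopifnot(nrow(data) > 0, all(c("arm", "bv", "tv_class") %in% names(data)))
  cells <- expand.grid(bv = unique(data$bv), arm = unique(data$arm),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- data[data$bv == cells$bv[i] & data$arm == cells$arm[i], ]
    n <- nrow(d)
    cnt <- c(hypo = sum(d$tv_class == "hypo"),
             optimal = sum(d$tv_class == "optimal"),
             hyper = sum(d$tv_class == "hyper"))
    pct <- proportions_from_counts(cnt)
    vi <- d$vi_ok[!is.na(d$vi_ok)]
    data.frame(bv = cells$bv[i], arm = cells$arm[i], n_ventilations = n,
               tv_hypo = cnt[["hypo"]], tv_optimal = cnt[["optimal"]],
               tv_hyper = cnt[["hyper"]],
               tv_hypo_pct = pct[["hypo"]], tv_optimal_pct = pct[["optimal"]],
               tv_hyper_pct = pct[["hyper"]],
               n_intervals = length(vi),
               vi_optimal = sum(vi),
               vi_optimal_pct = if (length(vi))
                 round(100 * mean(vi), 2) else NA_real_)
  }))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, `(r-1)(k-1)` degrees of
#' freedom; all expected counts must be positive.
#'
#' @param table Matrix of counts (e.g. 2 x k).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("expected counts must all be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` for a 2 x 2 table `rbind(c(a, b), c(c, d))`, with the
#' Woolf (log-OR normal) interval
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells get the
#' Haldane 0.5 continuity correction and the result is flagged. Ignores
#' any clustering, so it is a diagnostic companion to, not a substitute
#' for, a marginal-model odds ratio.
#'
#' @param table 2 x 2 count matrix.
#' @param level Confidence level.
#' @return List with `or`, `ci_lower`, `ci_upper`, `corrected`.
#' @examples
#' crude_odds_ratio(rbind(c(262, 292), c(98, 433)))  # ~3.96
#' @export
crude_odds_ratio <- function(table, level = 0.95) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  corrected <- any(table == 0)
  if (corrected) table <- table + 0.5
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  se <- sqrt(sum(1 / table))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, ci_lower = or * exp(-z * se), ci_upper = or * exp(z * se),
       corrected = corrected)
}

#' Marginal logistic model for trial adequacy outcomes
#'
#' Spec'd front-end over [gee_logit()]: fits a population-averaged logistic
#' model of an adequacy outcome on device assistance (`arm == "RAV"`), bag
#' type (`bv == "paediatric"`) and optionally their interaction, clustered
#' by participant. Rows with a missing outcome (the last breath of each
#' session has no interval) are dropped.
#'
#' @param data Long-format trial data frame: columns `participant`, `arm`,
#'   `bv`, `period`, and the binary outcomes `tv_ok`, `vi_ok`.
#' @param outcome `"tv_ok"` or `"vi_ok"`.
#' @param terms Any subset of `c("device", "bv_type", "interaction")`;
#'   `"interaction"` adds the device-by-bag-type product term.
#' @param correlation Working correlation passed to [gee_logit()].
#' @param include_period Add a crossover-period main effect (off by
#'   default; the primary model uses only device, bag type and their
#'   interaction).
#' @return A [gee_logit()] fit.
#' @export
fit_marginal_logistic <- function(data, outcome = c("tv_ok", "vi_ok"),
                                  terms = c("device", "bv_type"),
                                  correlation = c("exchangeable",
                                                  "independence"),
                                  include_period = FALSE) {
  outcome <- match.arg(outcome)
  correlation <- match.arg(correlation)
  bad <- setdiff(terms, c("device", "bv_type", "interaction"))
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  if (!length(terms)) stop("at least one model term is required")
  d <- data
  d$.y <- d[[outcome]]
  d$device <- as.integer(d$arm == "RAV")
  d$bv_paediatric <- as.integer(d$bv == "paediatric")
  rhs <- c(if ("device" %in% terms) "device",
           if ("bv_type" %in% terms) "bv_paediatric",
           if ("interaction" %in% terms) "device:bv_paediatric",
           if (include_period) "factor(period)")
  f <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  gee_logit(f, d, id = "participant", corstr = correlation)
}

#' McNemar paired-proportions sample size
#'
#' Number of pairs needed to detect a difference between two paired
#' proportions via the conditional (Connett-Smith-McHugh) formula:
#' `n = ceil((z_{a/2} sqrt(psi) + z_b sqrt(psi - d^2))^2 / d^2)` with
#' `psi` the discordant-pair proportion and `d = p_a - p_b`.
#'
#' @param p_a,p_b The two paired proportions (in (0,1)).
#' @param discordant Proportion of discordant pairs `psi`; must satisfy
#'   `|p_a - p_b| <= psi` and `psi > d^2`.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer number of pairs.
#' @examples
#' mcnemar_sample_size(0.85, 0.35, discordant = 0.5)          # 14
#' mcnemar_sample_size(0.85, 0.35, 0.5, alpha = 0.025)        # 17
#' @export
mcnemar_sample_size <- function(p_a, p_b, discordant = 0.5,
                                alpha = 0.05, power = 0.80) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1,
            discordant > 0, discordant < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  d <- p_a - p_b
  if (abs(d) > discordant)
    stop("|p_a - p_b| cannot exceed the discordant proportion")
  if (discordant <= d^2)
    stop("discordant proportion must exceed (p_a - p_b)^2")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(ceiling((za * sqrt(discordant) +
                      zb * sqrt(discordant - d^2))^2 / d^2))
}

#' Operator behaviour models for the crossover arms
#'
#' Per arm x bag-type squeeze-volume and interval means/SDs used by
#' [simulate_trial()]. The defaults are the observed per-arm session
#' statistics of the study (device-assisted operators deliver volumes near
#' the optimal range with much smaller spread).
#'
#' @return Nested list `models[[arm]][[bv_type]]` with elements `tv_mean`,
#'   `tv_sd`, `interval_mean`, `interval_sd`.
#' @export
default_operator_models <- function() {
  list(
    RAV = list(
      adult = list(tv_mean = 432.00, tv_sd = 63.93,
                   interval_mean = 6.84, interval_sd = 1.13),
      paediatric = list(tv_mean = 144.84, tv_sd = 23.07,
                        interval_mean = 6.57, interval_sd = 0.99)),
    NV = list(
      adult = list(tv_mean = 392.83, tv_sd = 136.36,
                   interval_mean = 6.37, interval_sd = 3.17),
      paediatric = list(tv_mean = 131.74, tv_sd = 38.78,
                        interval_mean = 6.29, interval_sd = 2.23)))
}

#' Simulate a full crossover trial
#'
#' Runs the whole pipeline for a two-period crossover: half the
#' participants perform device-assisted (RAV) sessions first, half
#' non-assisted (NV) first; every participant performs a 2-minute session
#' with each bag size in each period, crossing arms between periods. Each
#' session generates an operator-variable bag-squeeze trace, feeds it
#' through the device emulator, and classifies every detected ventilation.
#'
#' @param n_participants Number of participants (split as evenly as
#'   possible between the two sequence groups).
#' @param operator_models Arm-specific operator behaviour, see
#'   [default_operator_models()].
#' @param duration Session length (s).
#' @param cfg A [device_config()].
#' @param model A [sensor_model()].
#' @param thresholds A [threshold_set()].
#' @param squeeze_profile,squeeze_time Squeeze shape passed to the
#'   waveform generator.
#' @param seed Integer seed; the whole trial is reproducible given it.
#' @return Long-format data frame, one row per detected ventilation:
#'   `participant`, `arm`, `bv`, `period`, `breath_idx`, `tv_ml`,
#'   `interval_s`, `tv_class`, `tv_ok`, `vi_ok` (`NA` for each session's
#'   last breath).
#' @export
simulate_trial <- function(n_participants = 26,
                           operator_models = default_operator_models(),
                           duration = 120,
                           cfg = device_config(),
                           model = sensor_model(),
                           thresholds = threshold_set(),
                           squeeze_profile = "half_sine",
                           squeeze_time = 1,
                           seed = NULL) {
  stopifnot(n_participants >= 2)
  base <- if (is.null(seed)) sample.int(1e6, 1) else as.integer(seed)
  n_first <- ceiling(n_participants / 2)
  rows <- list()
  for (pid in seq_len(n_participants)) {
    rav_first <- pid <= n_first
    for (period in 1:2) {
      arm <- if (xor(rav_first, period == 2)) "RAV" else "NV"
      for (bv_i in 1:2) {
        bv <- c("adult", "paediatric")[bv_i]
        op <- operator_models[[arm]][[bv]]
        sp <- waveform_spec(
          "bagvalve", duration = duration,
          squeeze_profile = squeeze_profile, squeeze_time = squeeze_time,
          operator_tv_mean = op$tv_mean, operator_tv_sd = op$tv_sd,
          operator_interval_mean = op$interval_mean,
          operator_interval_sd = op$interval_sd,
          bv_type = bv,
          seed = (base + 1009L * pid + 101L * period + 11L * bv_i) %%
            .Machine$integer.max)
        tr <- suppressWarnings(gen_bagvalve_trace(sp, model))
        br <- detect_breaths(sample_and_quantize(tr, cfg), cfg)
        if (nrow(br) == 0) next
        cls <- classify_tv(br$tv_ml, bv, thresholds)
        vi <- classify_vi(br$interval_s, thresholds)
        rows[[length(rows) + 1]] <- data.frame(
          participant = pid, arm = arm, bv = bv, period = period,
          breath_idx = seq_len(nrow(br)),
          tv_ml = br$tv_ml, interval_s = br$interval_s,
          tv_class = as.character(cls),
          tv_ok = as.character(cls) == "optimal",
          vi_ok = ifelse(is.na(vi), NA, vi == "optimal"))
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate clustered binary outcomes with a known marginal odds ratio
#'
#' Generator for checking marginal-model recovery: each cluster contributes
#' `n_per_condition` binary outcomes under each of two conditions
#' (`x = 0, 1`) with marginal probabilities `p0` and `p1(or)`. Within a
#' cluster, exchangeable correlation `rho` is induced by letting each
#' observation copy a cluster-level draw with probability `sqrt(rho)` (the
#' cluster draw is thresholded from one shared uniform, so outcomes are
#' also positively correlated across conditions). Marginal probabilities,
#' and hence the marginal odds ratio, are exact by construction.
#'
#' @param n_clusters Number of clusters.
#' @param n_per_condition Observations per condition per cluster.
#' @param p0 Marginal outcome probability at `x = 0`.
#' @param or True marginal odds ratio of `x = 1` vs `x = 0`.
#' @param rho Within-condition exchangeable correlation (in `[0, 1)`).
#' @param seed Integer seed.
#' @return Data frame `id`, `x`, `y`.
#' @export
simulate_clustered_binary <- function(n_clusters, n_per_condition = 4,
                                      p0 = 0.3, or = 3.9, rho = 0.2,
                                      seed = NULL) {
  stopifnot(n_clusters >= 2, n_per_condition >= 1,
            p0 > 0, p0 < 1, or > 0, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  p1 <- stats::plogis(stats::qlogis(p0) + log(or))
  n_row <- n_clusters * 2 * n_per_condition
  id <- rep(seq_len(n_clusters), each = 2 * n_per_condition)
  x <- rep(rep(c(0L, 1L), each = n_per_condition), times = n_clusters)
  p <- ifelse(x == 1, p1, p0)
  u_cluster <- stats::runif(n_clusters)[id]     # shared cluster uniform
  v <- as.integer(u_cluster < p)                # cluster-level outcome
  w <- stats::rbinom(n_row, 1, p)               # independent outcome
  b <- stats::rbinom(n_row, 1, sqrt(rho))       # mixing indicator
  data.frame(id = id, x = x, y = b * v + (1 - b) * w)
}
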