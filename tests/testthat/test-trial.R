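test_that("printed adequacy counts reproduce the printed percentages", {
  t3 <- published_adequacy_counts()
  expect_equal(unname(proportions_from_counts(t3$adult$RAV)),
               c(47.29, 39.71, 13.00))
  expect_equal(unname(proportions_from_counts(t3$adult$NV)),
               c(18.46, 58.19, 23.35))
  expect_equal(unname(proportions_from_counts(t3$paediatric$RAV)),
               c(89.51, 9.58, 0.90))
  expect_equal(unname(proportions_from_counts(t3$paediatric$NV)),
               c(72.66, 25.05, 2.29))
  for (bv in c("adult", "paediatric")) for (arm in c("RAV", "NV")) {
    vi <- t3$vi[[bv]][[arm]]
    pct <- proportions_from_counts(c(vi[["optimal"]],
                                     vi[["total"]] - vi[["optimal"]]))
    expect_equal(unname(pct[1]),
                 c(adult.RAV = 95.64, adult.NV = 50.20,
                   paediatric.RAV = 95.83, paediatric.NV = 57.14
                 )[[paste(bv, arm, sep = ".")]])
  }
})

test_that("the long-format proportions table partitions every ventilation", {
  mk <- function(arm, bv, counts, vi_opt, vi_tot) {
    cls <- rep(c("optimal", "hypo", "hyper"), counts)
    n <- length(cls)
    vi <- c(rep(TRUE, vi_opt), rep(FALSE, vi_tot - vi_opt),
            rep(NA, n - vi_tot))
    data.frame(participant = 1, arm = arm, bv = bv, period = 1,
               breath_idx = seq_len(n), tv_class = cls,
               tv_ok = cls == "optimal", vi_ok = vi)
  }
  t3 <- published_adequacy_counts()
  d <- rbind(mk("RAV", "adult", t3$adult$RAV, 505, 528),
             mk("NV", "adult", t3$adult$NV, 254, 506),
             mk("RAV", "paediatric", t3$paediatric$RAV, 506, 528),
             mk("NV", "paediatric", t3$paediatric$NV, 284, 497))
  tab <- proportions_table(d)
  ar <- tab[tab$bv == "adult" & tab$arm == "RAV", ]
  expect_equal(ar$tv_optimal_pct, 47.29)
  expect_equal(ar$tv_hypo_pct, 39.71)
  expect_equal(ar$vi_optimal_pct, 95.64)
  expect_equal(ar$tv_hypo + ar$tv_optimal + ar$tv_hyper, ar$n_ventilations)
  pn <- tab[tab$bv == "paediatric" & tab$arm == "NV", ]
  expect_equal(pn$tv_optimal_pct, 72.66)
  expect_equal(pn$vi_optimal_pct, 57.14)

  single <- d[d$arm == "RAV" & d$bv == "adult" & d$tv_class == "optimal", ][1, ]
  expect_equal(proportions_table(single)$tv_optimal_pct, 100)
})

test_that("chi-square matches the direct Pearson formula", {
  tab <- rbind(c(262, 292), c(98, 433))
  res <- chi_square_2xk(tab)
  # oracle: Pearson statistic computed from first principles
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, stat_hand)
  expect_gt(res$statistic, 100)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$df, 1)
  # identical rows carry no signal
  res0 <- chi_square_2xk(rbind(c(30, 70), c(30, 70)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # doubling every cell doubles the statistic
  expect_equal(chi_square_2xk(2 * tab)$statistic, 2 * res$statistic)
  expect_error(chi_square_2xk(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("crude odds ratio follows the cross-product and Woolf interval", {
  res <- crude_odds_ratio(rbind(c(262, 292), c(98, 433)))
  expect_equal(res$or, (262 * 433) / (292 * 98))
  expect_equal(res$or, 3.9644, tolerance = 1e-4)
  expect_false(res$corrected)
  se <- sqrt(1 / 262 + 1 / 292 + 1 / 98 + 1 / 433)
  expect_equal(res$ci_lower, res$or * exp(-qnorm(0.975) * se))
  # symmetric table
  expect_equal(crude_odds_ratio(rbind(c(50, 50), c(50, 50)))$or, 1)
  # swapping rows inverts the ratio
  swapped <- crude_odds_ratio(rbind(c(98, 433), c(262, 292)))
  expect_equal(swapped$or, 1 / res$or)
  # zero cell: continuity corrected and flagged
  z <- crude_odds_ratio(rbind(c(10, 0), c(5, 8)))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
})

test_that("McNemar sample size follows the conditional formula", {
  expect_equal(mcnemar_sample_size(0.85, 0.35, discordant = 0.5,
                                   alpha = 0.05, power = 0.80), 14L)
  # hand evaluation with z = 1.96, z_beta = 0.8416
  n_hand <- ceiling((qnorm(0.975) * sqrt(0.5) +
                     qnorm(0.8) * sqrt(0.5 - 0.25))^2 / 0.25)
  expect_equal(mcnemar_sample_size(0.85, 0.35, 0.5), as.integer(n_hand))
  # more power can never need fewer pairs
  ns <- sapply(c(0.5, 0.7, 0.8, 0.9, 0.99),
               function(p) mcnemar_sample_size(0.6, 0.4, 0.5, power = p))
  expect_true(all(diff(ns) >= 0))
  # vanishing effect blows the requirement up
  expect_gt(mcnemar_sample_size(0.501, 0.5, 0.5), 1e5)
  expect_error(mcnemar_sample_size(0.9, 0.1, discordant = 0.5), "exceed")
})

test_that("simulated trials honour the crossover design", {
  d <- simulate_trial(n_participants = 4, duration = 40, seed = 55)
  # every participant serves both arms and both bag sizes
  for (pid in unique(d$participant)) {
    dp <- d[d$participant == pid, ]
    expect_setequal(unique(dp$arm), c("RAV", "NV"))
    expect_setequal(unique(dp$bv), c("adult", "paediatric"))
    # arms swap between periods
    expect_equal(length(unique(dp$arm[dp$period == 1])), 1)
    expect_false(unique(dp$arm[dp$period == 1]) ==
                 unique(dp$arm[dp$period == 2]))
  }
  # first half of the cohort is device-assisted first
  expect_equal(unique(d$arm[d$participant == 1 & d$period == 1]), "RAV")
  expect_equal(unique(d$arm[d$participant == 4 & d$period == 1]), "NV")
  # reproducibility
  expect_identical(d, simulate_trial(n_participants = 4, duration = 40,
                                     seed = 55))
})

test_that("perfect zero-variance operators are always adequate", {
  op <- list(tv_mean = 450, tv_sd = 0, interval_mean = 6.5, interval_sd = 0)
  models <- list(RAV = list(adult = op, paediatric = op),
                 NV = list(adult = op, paediatric = op))
  d <- simulate_trial(n_participants = 2, duration = 60,
                      operator_models = models, seed = 1)
  d_ad <- d[d$bv == "adult", ]
  expect_true(all(d_ad$tv_ok))
  expect_true(all(d_ad$vi_ok[!is.na(d_ad$vi_ok)]))
})

test_that("unassisted adult sessions land near the study's optimal-TV rate", {
  # operator volumes ~ truncated normal(392.83, 136.36): under a normal
  # approximation the optimal 420-480 mL share is ~16 %; the study observed
  # 18.46 %. The simulated full pipeline must land within 6 points.
  op <- default_operator_models()
  models <- list(RAV = op$NV, NV = op$NV)  # NV behaviour in both arms
  d <- simulate_trial(n_participants = 16, duration = 120,
                      operator_models = models, seed = 2024)
  d_ad <- d[d$bv == "adult", ]
  prop <- 100 * mean(d_ad$tv_ok)
  expect_gt(nrow(d_ad), 500)
  expect_lt(abs(prop - 18.46), 6)
})
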