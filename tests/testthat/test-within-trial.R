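test_that("adjusted difference collapses to the difference in arm means", {
  tb <- flat_two_arm_table()
  # identical outcomes in both arms -> difference exactly 0
  res <- adjusted_difference(tb, "y")
  expect_equal(res$estimate, 0)
  # no covariates, identity link -> equals difference in means
  tb$y <- ifelse(tb$arm == "incentives", 120, 95) + rep(c(0, 2), 20)
  res <- adjusted_difference(tb, "y")
  expect_equal(res$estimate,
               mean(tb$y[tb$arm == "incentives"]) -
                 mean(tb$y[tb$arm == "control"]))
})

test_that("gamma/log cost model falls back to Gaussian on non-positive costs", {
  tb <- flat_two_arm_table()
  tb$y <- c(rep(0, 5), runif(35, 50, 150))
  res <- adjusted_difference(tb, "y", family_spec = "gamma_log")
  expect_equal(res$family_used, "gaussian_identity")
  tb$y <- runif(40, 50, 150)
  res2 <- adjusted_difference(tb, "y", family_spec = "gamma_log")
  expect_equal(res2$family_used, "gamma_log")
})

test_that("a built-in arm cost effect is recovered within the interval", {
  # null generator (equal arms, vouchers off) plus an exact +£500 shift
  eq <- c(incentives = 0.2, control = 0.2)
  spec <- cohort_spec(n_incentives = 2500L, n_control = 2500L,
                      engage_prob = c(incentives = 0.6, control = 0.6),
                      quit_prob_4wk = eq, quit_prob_12wk = eq,
                      quit_prob_late = eq,
                      quit_prob_late_selfreport = eq,
                      quit_prob_postpartum = c(incentives = 0.1, control = 0.1),
                      late_award_prob = 0.2,
                      nrt_weeks_mean = c(incentives = 3.5, control = 3.5),
                      sss_minutes_mean = c(incentives = 60, control = 60),
                      seed = 55L)
  off <- voucher_schedule(engagement_amount = 0, quit4_amount = 0,
                          quit12_amount = 0, late_amount = 0,
                          postage_per_voucher = 0, resend_postage = 0)
  ct <- cost_participants(generate_cohort(spec), off)
  ct$cost_total <- ct$cost_total + 500 * (ct$arm == "incentives")
  res <- adjusted_difference(ct, "cost_total",
                             c("site", "age_years", "years_smoking",
                               "covid_era"), "gamma_log")
  expect_gt(res$ci[2], 500)
  expect_lt(res$ci[1], 500)
})

test_that("ICERs classify dominance and round for reporting", {
  base <- icer(637, 0.144)
  expect_equal(base$label, "ratio")
  expect_equal(base$value, 637 / 0.144)
  expect_equal(base$reported, 4400)
  expect_equal(icer(637, 0.174)$reported, 3700)
  expect_equal(icer(-37, 0.171)$label, "dominant")
  expect_equal(icer(100, -0.1)$label, "dominated")
  expect_equal(icer(100, 0)$label, "undefined")
  # savings with losses still reports the ratio
  expect_equal(icer(-100, -0.05)$label, "ratio")
  expect_equal(round_icer(4423.6), 4400)
  expect_equal(round_icer(23592.6), 24000)
  expect_equal(round_icer(106166.7), 106000)
  expect_true(is.na(round_icer(NA_real_)))
})

test_that("printed-ICER inconsistencies are flagged, consistent cells are not", {
  expect_false(icer_consistency_flag(637, 0.144, 4400))
  expect_false(icer_consistency_flag(644, 0.144, 4500))
  # equalized-neonatal scenario: printed ratio irreproducible from inputs
  expect_true(icer_consistency_flag(176, 0.144, 4500))
  # cost-per-QALY cell: printed rounded inputs give a different ratio
  expect_true(icer_consistency_flag(637, 0.004, 150000))
})

test_that("gaming deflation is proportional, monotone and identity at zero", {
  expect_equal(adjust_for_gaming(0.268, 0.11), 0.23852)
  expect_equal(round(adjust_for_gaming(0.268, 0.11), 3), 0.239)
  expect_equal(round(adjust_for_gaming(0.123, 0.20), 3), 0.098)
  expect_equal(round(adjust_for_gaming(0.123, 0.11), 3), 0.109)
  expect_equal(adjust_for_gaming(0.5, 0), 0.5)
  fs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(adjust_for_gaming(0.3, fs)) < 0))
  expect_error(adjust_for_gaming(0.3, 1.2), "fraction")
})

test_that("bootstrap is degenerate on constant data and seed-reproducible", {
  tb <- flat_two_arm_table(n_per_arm = 30)
  tb$cost_total <- 100
  tb$qaly_late <- 0.3
  cfg <- analysis_config(bootstrap_reps = 25L, seed = 9L,
                         cost_covariates = character(),
                         qaly_covariates = character(),
                         cost_family = "gaussian_identity")
  s <- bootstrap_cea(tb, cfg)
  expect_equal(nrow(s), 25)
  expect_true(all(abs(s$delta_cost) < 1e-8))
  expect_true(all(abs(s$delta_effect) < 1e-10))
  # fixed seed -> identical sample set
  tb$cost_total <- tb$cost_total + rep(seq(0, 29), 2)
  s1 <- bootstrap_cea(tb, cfg)
  s2 <- bootstrap_cea(tb, cfg)
  expect_identical(s1, s2)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(bootstrap_cea(tb, cfg2), s1))
})

test_that("CEAC equals brute-force enumeration and P(saving) at lambda 0", {
  hand <- tibble::tibble(delta_cost = c(-100, 200, 50, -10),
                         delta_effect = c(0.1, 0.2, -0.05, 0))
  grid <- c(0, 1000, 5000)
  curve <- ceac(hand, grid)
  brute <- vapply(grid, function(l) {
    mean(l * hand$delta_effect - hand$delta_cost > 0)
  }, numeric(1))
  expect_equal(curve$probability, brute)
  expect_equal(curve$probability[1], mean(hand$delta_cost < 0))
  # all-dominant samples: probability 1 at every threshold
  dom <- tibble::tibble(delta_cost = c(-5, -10), delta_effect = c(0.1, 0.2))
  expect_true(all(ceac(dom, grid)$probability == 1))
  expect_error(ceac(hand, numeric(0)), "grid")
  expect_error(ceac(hand[0, ], grid), "sample")
})

test_that("ICER classification agrees with NMB sign at the reference threshold", {
  set.seed(123)
  samples <- tibble::tibble(delta_cost = rnorm(200, 100, 400),
                            delta_effect = rnorm(200, 0.05, 0.1))
  lambda <- 20000
  for (i in seq_len(nrow(samples))) {
    ic <- icer(samples$delta_cost[i], samples$delta_effect[i])
    nmb <- lambda * samples$delta_effect[i] - samples$delta_cost[i]
    if (ic$label == "dominant") expect_gt(nmb, 0)
    if (ic$label == "dominated") expect_lt(nmb, 0)
    if (ic$label == "ratio" && samples$delta_effect[i] > 0) {
      expect_equal(nmb > 0, ic$value < lambda)
    }
  }
})

test_that("arm-unbalanced cost shifts lower the CEAC; balanced shifts do not", {
  tb <- attach_outcomes(cost_participants(generate_cohort(small_spec(7L))))
  cfg <- analysis_config(bootstrap_reps = 40L, seed = 2L,
                         cost_covariates = character(),
                         qaly_covariates = character(),
                         cost_family = "gaussian_identity",
                         wtp_grid = seq(0, 40000, 10000))
  s0 <- bootstrap_cea(tb, cfg)
  # balanced: add £300 to both arms -> identical deltas
  tb_bal <- tb; tb_bal$cost_total <- tb_bal$cost_total + 300
  expect_equal(bootstrap_cea(tb_bal, cfg)$delta_cost, s0$delta_cost,
               tolerance = 1e-8)
  # unbalanced: add £300 to incentives arm only -> curve weakly lower
  tb_shift <- tb
  tb_shift$cost_total <- tb_shift$cost_total +
    300 * (tb_shift$arm == "incentives")
  c_shift <- ceac(bootstrap_cea(tb_shift, cfg), cfg$wtp_grid)
  c_base <- ceac(s0, cfg$wtp_grid)
  expect_true(all(c_shift$probability <= c_base$probability))
  expect_true(any(c_shift$probability < c_base$probability))
})

test_that("scenario registry rejects unknown ids and matches the base case", {
  tb <- simulate_trial(small_spec(21L))
  cfg <- analysis_config(n_imputations = 2L, seed = 3L)
  expect_error(run_scenarios(tb, cfg, scenarios = "S99"), "S99")
  res <- run_scenarios(tb, cfg, scenarios = c("base", "S3", "S4", "S10"))
  expect_equal(nrow(res), 4)
  base <- res[res$scenario == "base", ]
  s3 <- res[res$scenario == "S3", ]
  s4 <- res[res$scenario == "S4", ]
  # gaming scenarios deflate the base-case rates proportionally
  expect_equal(s3$quit_rate_incentives,
               0.89 * base$quit_rate_incentives)
  expect_equal(s3$quit_rate_control, 0.80 * base$quit_rate_control)
  expect_equal(s4$quit_rate_control, 0.89 * base$quit_rate_control)
  # gaming keeps the base-case incremental cost
  expect_equal(s3$delta_cost, base$delta_cost)
})
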