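test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(10, 0.035), 1.035^-10)
  # constant stream of 1 for T years: geometric series
  T_ <- 25; r <- 0.035
  stream <- sum(discount_factor(1:T_, r))
  closed <- (1 - (1 + r)^-T_) / r
  expect_equal(stream, closed)
  expect_error(discount_factor(-1, 0.035), "years")
  expect_error(discount_factor(1, -1.5), "rate")
})

test_that("relapse extrapolation supports all three methods", {
  expect_equal(extrapolate_relapse(0, "constant_hazard"), 0)
  expect_equal(extrapolate_relapse(0.5, "constant_hazard"), 0.75)
  expect_equal(extrapolate_relapse(0.3, "passthrough"), 0.3)
  expect_equal(extrapolate_relapse(0.3, "fixed", fixed_value = 0.814), 0.814)
  expect_error(extrapolate_relapse(0.3, "spline"), "method")
  expect_error(extrapolate_relapse(1.3), "rate_6mo")
})

test_that("Markov engine accumulates rewards and conserves mass", {
  # single alive state, utility 1, no death, no discount: 10 QALYs
  one <- run_markov(init = c(alive = 1), n_cycles = 10,
                    transition = function(c) matrix(1, 1, 1),
                    cost = function(c) c(alive = 0),
                    utility = function(c) c(alive = 1),
                    discount_rate = 0)
  expect_equal(one$qaly, 10)
  # constant mortality: finite-horizon geometric closed form
  m <- 0.2; T_ <- 40
  surv <- run_markov(init = c(alive = 1, dead = 0), n_cycles = T_,
                     transition = function(c) {
                       rbind(c(1 - m, m), c(0, 1))
                     },
                     cost = function(c) c(0, 0),
                     utility = function(c) c(1, 0),
                     discount_rate = 0)
  closed <- sum((1 - m)^(1:T_))
  expect_equal(surv$qaly, closed)
  # everyone dead at entry: zero accumulation
  dead <- run_markov(init = c(alive = 0, dead = 1), n_cycles = 5,
                     transition = function(c) rbind(c(1, 0), c(0, 1)),
                     cost = function(c) c(100, 0),
                     utility = function(c) c(1, 0),
                     discount_rate = 0)
  expect_equal(dead$cost, 0)
  expect_equal(dead$qaly, 0)
  # malformed transitions are rejected
  expect_error(run_markov(c(a = 1, dead = 0), 2,
                          function(c) rbind(c(0.5, 0.4), c(0, 1)),
                          function(c) c(0, 0), function(c) c(1, 0)),
               "sum to 1")
  expect_error(run_markov(c(a = 1, dead = 0), 2,
                          function(c) rbind(c(0.5, 0.5), c(0.1, 0.9)),
                          function(c) c(0, 0), function(c) c(1, 0)),
               "absorbing")
})

test_that("half-cycle correction credits the mean of entry and exit occupancy", {
  m <- 0.5
  tr <- function(c) rbind(c(1 - m, m), c(0, 1))
  full <- run_markov(c(alive = 1, dead = 0), 1, tr,
                     function(c) c(0, 0), function(c) c(1, 0),
                     discount_rate = 0)
  half <- run_markov(c(alive = 1, dead = 0), 1, tr,
                     function(c) c(0, 0), function(c) c(1, 0),
                     discount_rate = 0, half_cycle = TRUE)
  expect_equal(full$qaly, 0.5)
  expect_equal(half$qaly, 0.75)
})

test_that("pregnancy tree expectation matches hand enumeration", {
  p <- fast_lifetime_params()
  # equal quit rates in both arms: zero incremental outcomes
  p_eq <- p
  p_eq$quit_rate <- c(incentives = 0.2, control = 0.2)
  p_eq$intervention_cost <- c(incentives = 100, control = 100)
  t_inc <- run_pregnancy_tree(p_eq, "incentives")
  t_ctl <- run_pregnancy_tree(p_eq, "control")
  expect_equal(t_inc$mother_cost, t_ctl$mother_cost)
  expect_equal(t_inc$adverse_live_births, t_ctl$adverse_live_births)
  # two-branch toy: hand-computed expectation
  q <- 0.25
  p2 <- p
  p2$quit_rate[["incentives"]] <- q
  tree <- run_pregnancy_tree(p2, "incentives")
  po <- p2$pregnancy_outcome_probs
  mix <- q * po["quit", ] + (1 - q) * po["smoker", ]
  expect_equal(tree$infant_cost,
               sum(mix * p2$pregnancy_outcome_cost))
  expect_equal(tree$mother_cost,
               p2$intervention_cost[["incentives"]] +
                 q * p2$maternity_cost[["quit"]] +
                 (1 - q) * p2$maternity_cost[["smoker"]])
  expect_equal(tree$adverse_pregnancy_outcomes,
               p2$cohort_size * (mix[["adverse_live"]] + mix[["loss"]]))
  # higher quit rate cannot raise adverse counts
  lo <- run_pregnancy_tree(p2, "control")  # control rate 0.123 < 0.25
  expect_lte(tree$adverse_live_births, lo$adverse_live_births)
})

test_that("lifetime traces conserve cohort mass with no negative occupancy", {
  p <- lifetime_params()
  for (arm in c("incentives", "control")) {
    mother <- quitinc:::mother_section(p, arm)
    expect_true(all(abs(rowSums(mother$trace) - 1) < 1e-9))
    expect_true(all(mother$trace >= -1e-12))
    tree <- run_pregnancy_tree(p, arm)
    child <- quitinc:::infant_childhood_section(p, arm, tree)
    expect_true(all(abs(rowSums(child$trace) - 1) < 1e-9))
    adult <- quitinc:::infant_adulthood_section(p, arm, child)
    expect_true(all(abs(rowSums(adult$trace) - 1) < 1e-9))
    expect_true(all(adult$trace >= -1e-12))
  }
})

test_that("zero discounting reproduces the straight undiscounted sum", {
  p <- fast_lifetime_params(discount_rate = 0)
  mother <- quitinc:::mother_section(p, "incentives")
  # manual accumulation from the trace
  manual <- 0
  for (cyc in 1:(p$max_age - p$mother_age)) {
    bi <- findInterval(p$mother_age + cyc, p$age_bands)
    u <- c(p$state_utilities$quitter[bi], p$state_utilities$smoker[bi], 0)
    manual <- manual + sum(mother$trace[cyc + 1, ] * u)
  }
  expect_equal(mother$qaly, manual)
})

test_that("combined results satisfy the accounting identity and dominance rule", {
  res <- run_lifetime(lifetime_params())
  comb <- res[res$scenario == "combined", ]
  ml <- res[res$scenario == "maternal_lifetime", ]
  ia <- res[res$scenario == "infant_adulthood", ]
  expect_equal(comb$delta_cost, ml$delta_cost + ia$delta_cost)
  expect_equal(comb$delta_qaly, ml$delta_qaly + ia$delta_qaly)
  # dominance labelling iff delta_cost < 0 < delta_qaly
  for (i in seq_len(nrow(res))) {
    should <- res$delta_cost[i] < 0 && res$delta_qaly[i] > 0
    expect_equal(res$icer_label[i] == "dominant", should)
  }
  # identical parameters in both arms: all incrementals vanish
  p0 <- lifetime_params()
  p0$quit_rate[["incentives"]] <- p0$quit_rate[["control"]]
  p0$intervention_cost[["incentives"]] <- p0$intervention_cost[["control"]]
  res0 <- run_lifetime(p0)
  expect_true(all(abs(res0$delta_cost) < 1e-9))
  expect_true(all(abs(res0$delta_qaly) < 1e-12))
})

test_that("combined QALY gain is monotone in the incentives quit rate", {
  p <- fast_lifetime_params()
  rates <- seq(0.10, 0.40, by = 0.06)
  gains <- vapply(rates, function(q) {
    p$quit_rate[["incentives"]] <- q
    res <- run_lifetime(p)
    res$delta_qaly[res$scenario == "combined"]
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("break-even intervention cost exists and separates dominance", {
  p <- lifetime_params()
  be <- break_even_intervention_cost(p)
  expect_true(is.finite(be$cost))
  expect_gt(be$cost, 0)
  below <- p; below$intervention_cost[["incentives"]] <- be$cost * 0.9
  above <- p; above$intervention_cost[["incentives"]] <- be$cost * 1.1
  res_b <- run_lifetime(below); res_a <- run_lifetime(above)
  expect_equal(res_b$icer_label[res_b$scenario == "combined"], "dominant")
  expect_gt(res_a$delta_cost[res_a$scenario == "combined"], 0)
})

test_that("lifetime scenario overlays substitute the published inputs", {
  p <- fast_lifetime_params()
  res <- run_all_scenarios(p, scenarios = c("base", "S1a", "S3a", "S4"))
  expect_equal(res$scenario, c("base", "S1a", "S3a", "S4"))
  expect_error(run_all_scenarios(p, scenarios = "S9"), "S9")
  # S1a deflates the quit rates before the run: lower QALY gain than base
  expect_lt(res$delta_qaly[res$scenario == "S1a"],
            res$delta_qaly[res$scenario == "base"])
  # S3a: £131 intervention with much lower quit rates
  p3 <- p
  p3$intervention_cost[["incentives"]] <- 131
  p3$quit_rate <- c(incentives = 0.046, control = 0.025)
  manual <- run_lifetime(p3)
  expect_equal(res$delta_cost[res$scenario == "S3a"],
               manual$delta_cost[manual$scenario == "combined"])
  # S4 raises first-year relapse: QALY gain shrinks
  expect_lt(res$delta_qaly[res$scenario == "S4"],
            res$delta_qaly[res$scenario == "base"])
})
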