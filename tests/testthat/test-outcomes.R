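test_that("Russell standard counts missing reports as smokers", {
  r <- russell_quit(NA)
  expect_equal(r$status, "smoker")
  expect_equal(r$basis, "imputed_smoker")
  expect_equal(russell_quit("quit", verified_flag = TRUE)$status, "quit")
  # reported quit but verification failed -> smoker
  expect_equal(russell_quit("quit", verified_flag = FALSE)$status, "smoker")
  # covid-era self-report with saliva passes the primary definition
  expect_equal(russell_quit("quit", verified_flag = NA, covid_era = TRUE,
                            saliva_provided = TRUE)$status, "quit")
  expect_equal(russell_quit("quit", verified_flag = NA, covid_era = TRUE,
                            saliva_provided = FALSE)$status, "smoker")
  # sensitivity definition takes self-report at face value
  expect_equal(russell_quit("quit", verified_flag = FALSE,
                            self_report = TRUE)$status, "quit")
  expect_equal(russell_quit(NA, self_report = TRUE)$status, "smoker")
})

test_that("Russell-rule quit rates never exceed complete-case rates", {
  spec <- cohort_spec(seed = 29L)
  tb <- generate_cohort(spec)
  masked <- inject_missingness(tb, c(quit_late = 0.10), seed = 29L)
  russell <- mean(russell_quit(masked$quit_late,
                               verified_flag = masked$quit_late == "quit")$status == "quit")
  cc <- mean(masked$quit_late[!is.na(masked$quit_late)] == "quit")
  expect_lte(russell, cc)
})

test_that("EQ-5D conversion anchors full health at 1 and applies decrements", {
  vs <- identity_valueset()
  expect_equal(eq5d_to_utility("11111", vs), 1)
  expect_equal(eq5d_to_utility(c("54321", "22222"), vs), c(1, 1))
  # one configured decrement of 0.1
  vs2 <- vs
  vs2$decrement[vs2$dimension == "MO" & vs2$level == 2] <- 0.1
  expect_equal(eq5d_to_utility("21111", vs2), 0.9)
  # additive across dimensions
  vs2$decrement[vs2$dimension == "PD" & vs2$level == 3] <- 0.25
  expect_equal(eq5d_to_utility("21131", vs2), 1 - 0.1 - 0.25)
  # lookup layout
  lk <- data.frame(profile = c("11111", "21111"), utility = c(1, 0.85))
  expect_equal(eq5d_to_utility("21111", lk), 0.85)
  expect_error(eq5d_to_utility("1111", vs), "profiles")
  expect_error(eq5d_to_utility("11611", vs), "profiles")
  expect_error(eq5d_to_utility("33333", lk), "value set")
})

test_that("QALY area under the curve is the trapezoid integral", {
  expect_equal(qaly_auc(c(0, 1), c(1, 1)), 1)
  expect_equal(qaly_auc(c(0, 0.4, 1), c(0, 0, 0)), 0)
  expect_equal(qaly_auc(c(0, 0.5), c(0.8, 0.6)), 0.35)
  # fewer than two observed points is undefined, not zero
  expect_true(is.na(qaly_auc(c(0, 0.5), c(0.8, NA))))
  expect_true(is.na(qaly_auc(c(0, 0.5, 1.15), c(NA, 0.7, NA))))
  # interior gap: linear bridge across the missing point
  expect_equal(qaly_auc(c(0, 0.5, 1), c(0.8, NA, 0.6)), 0.7)
  expect_error(qaly_auc(c(0, 0.5, 0.5), c(1, 1, 1)), "increasing")
})

test_that("QALY AUC is linear in utilities and bounded by max utility x time", {
  set.seed(77)
  for (i in 1:25) {
    t <- sort(runif(3, 0, 2)); t <- t + seq(0, 0.02, length.out = 3)
    u <- runif(3, -0.5, 1)
    auc <- qaly_auc(t, u)
    expect_equal(qaly_auc(t, 0.4 * u), 0.4 * auc)
    expect_lte(auc, max(u) * (max(t) - min(t)) + 1e-12)
  }
})

test_that("attach_outcomes derives Russell quits and both QALY horizons", {
  spec <- small_spec(seed = 3L)
  tb <- attach_outcomes(cost_participants(generate_cohort(spec)))
  expect_true(all(tb$quit_late_russell %in% 0:1))
  expect_equal(tb$quit_late_russell, as.integer(tb$quit_late == "quit"))
  # post-partum horizon adds the second-interval trapezoid
  second <- (tb$utility_late + tb$utility_postpartum) / 2 * tb$t_postpartum_years
  expect_equal(tb$qaly_postpartum - tb$qaly_late, second, tolerance = 1e-10)
  # self-report definition can only add quitters
  sr <- attach_outcomes(cost_participants(generate_cohort(spec)),
                        self_report = TRUE)
  expect_true(all(sr$quit_late_russell >= tb$quit_late_russell))
})
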