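test_that("voucher engine pays the schedule under the contingency rules", {
  # all four milestones -> the full £400
  expect_equal(voucher_awards(participant_record())$total, 400)
  # nothing achieved -> £0
  none <- participant_record(engaged = FALSE, quit_4wk = "smoker",
                             quit_12wk = "smoker", quit_late = "smoker")
  expect_equal(voucher_awards(none)$total, 0)
  # engagement only -> £50
  eng <- participant_record(quit_4wk = "smoker", quit_12wk = "smoker",
                            quit_late = "smoker")
  expect_equal(voucher_awards(eng)$total, 50)
  # late-pregnancy quit with no prior vouchers -> £200 only
  late_only <- participant_record(engaged = FALSE, quit_4wk = "smoker",
                                  quit_12wk = "smoker")
  expect_equal(voucher_awards(late_only)$total, 200)
  # the £100 requires the 4-week criteria (chain back to engagement)
  skip4 <- participant_record(quit_4wk = "smoker", quit_late = "smoker")
  expect_equal(voucher_awards(skip4)$total, 50)  # engagement only
  # missing milestone counts as not achieved
  na4 <- participant_record(quit_4wk = NA, quit_12wk = NA,
                            quit_late = "smoker")
  expect_equal(voucher_awards(na4)$total, 50)
})

test_that("covid-era self-report with saliva earns the late voucher", {
  rec <- participant_record(engaged = FALSE, quit_4wk = "smoker",
                            quit_12wk = "smoker", quit_late = "smoker",
                            quit_late_selfreport = "quit",
                            covid_era = TRUE, saliva_provided = TRUE)
  expect_equal(voucher_awards(rec)$total, 200)
  # without saliva, or pre-covid, no award
  rec$saliva_provided <- FALSE
  expect_equal(voucher_awards(rec)$total, 0)
  rec$saliva_provided <- TRUE; rec$covid_era <- FALSE
  expect_equal(voucher_awards(rec)$total, 0)
  # pathway can be disabled in the schedule
  rec$covid_era <- TRUE
  off <- voucher_schedule(covid_selfreport_allowed = FALSE)
  expect_equal(voucher_awards(rec, off)$total, 0)
})

test_that("voucher totals are monotone in achieved milestones", {
  combos <- expand.grid(eng = c(FALSE, TRUE), q4 = c(FALSE, TRUE),
                        q12 = c(FALSE, TRUE), late = c(FALSE, TRUE))
  total_of <- function(row) {
    voucher_awards(participant_record(
      engaged = row$eng,
      quit_4wk = if (row$q4) "quit" else "smoker",
      quit_12wk = if (row$q12) "quit" else "smoker",
      quit_late = if (row$late) "quit" else "smoker"))$total
  }
  totals <- apply(combos, 1, function(r) total_of(as.list(r)))
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      if (all(unlist(combos[i, ]) >= unlist(combos[j, ]))) {
        expect_gte(totals[i], totals[j])
      }
    }
  }
  # exclusion flag removes a voucher from the total but not the issue count
  full <- voucher_awards(participant_record(), exclude = "late_pregnancy")
  expect_equal(full$total, 200)
  expect_equal(full$n_issued, 4)
})

test_that("postage follows the per-voucher and re-send rates", {
  expect_equal(postage_cost(0, 0), 0)
  expect_equal(postage_cost(1, 0), 2.92)
  expect_equal(postage_cost(793, 59), 793 * 2.92 + 59 * 2.05)
  expect_equal(postage_cost(793, 59), 2436.51)
  expect_error(postage_cost(-1, 0), "counts")
})

test_that("neonatal cost is a non-increasing step function of gestational age", {
  expect_equal(neonatal_cost(38), 0)
  expect_equal(neonatal_cost(36), 13 * 536.45)
  expect_equal(neonatal_cost(30), 44 * 709.16)
  expect_equal(neonatal_cost(26), 93 * 1707.50)
  expect_equal(neonatal_cost(26), 158797.5)
  expect_true(is.na(neonatal_cost(NA)))
  expect_error(neonatal_cost(12), "gestational")
  grid <- seq(21, 44.5, by = 0.5)
  costs <- neonatal_cost(grid)
  expect_true(all(diff(costs) <= 0))
})

test_that("support costs use grade rates, weekly NRT price and site profiles", {
  uc <- unit_cost_table()
  r <- participant_record(sss_contact_minutes = 60, nrt_weeks = 0,
                          adviser_grade = 5L)
  expect_equal(support_costs(r, uc)$sss, 39)
  r0 <- participant_record(sss_contact_minutes = 0, nrt_weeks = 0)
  expect_equal(support_costs(r0, uc)$sss, 0)
  expect_equal(support_costs(r0, uc)$nrt, 0)
  r6 <- participant_record(sss_contact_minutes = 90, adviser_grade = 6L)
  expect_equal(support_costs(r6, uc)$sss, 73.5)
  expect_error(support_costs(participant_record(adviser_grade = 9L), uc),
               "grade")
  # typical-use site: missing values fall back to the site profile
  typ <- participant_record(site = 7L, sss_contact_minutes = NA,
                            nrt_weeks = NA, adviser_grade = 6L)
  sc <- support_costs(typ, uc)
  expect_equal(sc$sss, uc$site_profile$sss_contact_minutes / 60 * 49)
  expect_equal(sc$nrt, uc$site_profile$nrt_weeks * uc$nrt_cost_per_week)
  # non-typical site: missing stays missing (flows to imputation)
  ind <- participant_record(site = 1L, sss_contact_minutes = NA)
  expect_true(is.na(support_costs(ind, uc)$sss))
})

test_that("arm summaries compute means and standard errors correctly", {
  toy <- tibble::tibble(
    arm = c("incentives", "incentives"),
    cost_vouchers = c(100, 200), cost_postage = 0, cost_sss = 0,
    cost_nrt = 0, cost_intervention = c(100, 200), cost_neonatal = 0,
    cost_total = c(100, 200))
  s <- arm_cost_summary(toy)
  tot <- s[s$component == "cost_total", ]
  expect_equal(tot$mean, 150)
  expect_equal(tot$se, 50)
  expect_error(arm_cost_summary(toy[0, ]), "empty|arm")
})

test_that("vectorised costing agrees with the per-record operations", {
  tb <- generate_cohort(small_spec(seed = 4L))
  ct <- cost_participants(tb)
  for (i in seq(1, nrow(tb), by = 7)) {
    rec <- lapply(tb, `[[`, i)
    v <- if (rec$arm == "incentives") voucher_awards(rec)$total else 0
    sc <- support_costs(rec)
    expect_equal(unname(ct$cost_vouchers[i]), v)
    expect_equal(unname(ct$cost_sss[i]), sc$sss)
    expect_equal(unname(ct$cost_nrt[i]), sc$nrt)
  }
  expect_true(all(ct$cost_vouchers[ct$arm == "control"] == 0))
  expect_equal(ct$cost_total, ct$cost_intervention + ct$cost_neonatal,
               tolerance = 1e-10)
})

test_that("calibrated cohort reproduces the published voucher+postage mean", {
  spec <- cohort_spec(n_incentives = 9420L, n_control = 100L, seed = 8L)
  ct <- cost_participants(generate_cohort(spec))
  inc <- ct[ct$arm == "incentives", ]
  vp <- mean(inc$cost_vouchers + inc$cost_postage)
  expect_lt(abs(vp - 152), 5)
})
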