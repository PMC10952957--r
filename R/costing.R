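#' Contingent voucher schedule
#'
#' The incentive scheme pays shopping vouchers at four milestones:
#' engagement with stop smoking services plus setting a quit date (£50),
#' carbon-monoxide-verified quit at 4 weeks (£50) and 12 weeks (£100) post
#' quit date — each contingent on having met the criteria for the previous
#' voucher — and verified quit at late pregnancy (£200), which does not
#' require the earlier vouchers. After 16 March 2020 the late-pregnancy
#' voucher could be earned by self-report plus a saliva sample.
#'
#' @param engagement_amount,quit4_amount,quit12_amount,late_amount voucher
#'   values in pounds
#' @param quit4_requires_previous,quit12_requires_previous,late_requires_previous
#'   contingency flags linking each voucher to the previous milestone
#' @param covid_selfreport_allowed allow the covid-era self-report + saliva
#'   pathway for the late voucher
#' @param postage_per_voucher postage applied to every issued voucher
#' @param resend_postage charge applied to re-sent vouchers that incurred
#'   a fee
#' @return an object of class `voucher_schedule`
#' @export
voucher_schedule <- function(engagement_amount = 50,
                             quit4_amount = 50,
                             quit12_amount = 100,
                             late_amount = 200,
                             quit4_requires_previous = TRUE,
                             quit12_requires_previous = TRUE,
                             late_requires_previous = FALSE,
                             covid_selfreport_allowed = TRUE,
                             postage_per_voucher = 2.92,
                             resend_postage = 2.05) {
  amounts <- c(engagement_amount, quit4_amount, quit12_amount, late_amount,
               postage_per_voucher, resend_postage)
  if (any(amounts < 0)) stop_field("amounts", "all amounts must be >= 0")
  structure(list(
    engagement_amount = engagement_amount, quit4_amount = quit4_amount,
    quit12_amount = quit12_amount, late_amount = late_amount,
    quit4_requires_previous = quit4_requires_previous,
    quit12_requires_previous = quit12_requires_previous,
    late_requires_previous = late_requires_previous,
    covid_selfreport_allowed = covid_selfreport_allowed,
    postage_per_voucher = postage_per_voucher,
    resend_postage = resend_postage,
    max_total = engagement_amount + quit4_amount + quit12_amount + late_amount
  ), class = "voucher_schedule")
}

#' Unit cost table
#'
#' Unit costs at 2020 prices (GBP). Cessation advisers are costed per hour
#' by pay grade; NRT per prescribed week; neonatal stays by preterm class
#' as a per-day cost times a class length of stay (13 days moderate-to-late,
#' 44 very, 93 extremely preterm). The weekly NRT price is a configuration
#' default (the source formulary lists many preparations).
#'
#' @param adviser_rate_per_hour named vector, pounds per hour by grade
#' @param nrt_cost_per_week pounds per prescribed week of NRT
#' @param neonatal_per_day named vector of per-day neonatal costs by
#'   preterm class
#' @param neonatal_los_days named vector of lengths of stay (days) by class
#' @param typical_use_sites sites without individual support-use records;
#'   costed from the site profile when a participant's values are missing
#' @param site_profile list with `sss_contact_minutes` and `nrt_weeks`
#'   giving typical use at those sites
#' @param price_year,currency labels recorded in outputs
#' @return an object of class `unit_cost_table`
#' @export
unit_cost_table <- function(adviser_rate_per_hour = c(`5` = 39, `6` = 49),
                            nrt_cost_per_week = 16.50,
                            neonatal_per_day = c(moderate_late = 536.45,
                                                 very = 709.16,
                                                 extremely = 1707.50),
                            neonatal_los_days = c(moderate_late = 13,
                                                  very = 44,
                                                  extremely = 93),
                            typical_use_sites = c(6L, 7L),
                            site_profile = list(sss_contact_minutes = 60,
                                                nrt_weeks = 4),
                            price_year = 2020L,
                            currency = "GBP") {
  if (any(c(adviser_rate_per_hour, nrt_cost_per_week, neonatal_per_day) < 0)) {
    stop_field("unit_costs", "all costs must be >= 0")
  }
  cls <- c("moderate_late", "very", "extremely")
  if (!all(cls %in% names(neonatal_per_day)) ||
      !all(cls %in% names(neonatal_los_days))) {
    stop_field("neonatal_per_day",
               "each preterm class needs a per-day cost and a length of stay")
  }
  structure(list(
    adviser_rate_per_hour = adviser_rate_per_hour,
    nrt_cost_per_week = nrt_cost_per_week,
    neonatal_per_day = neonatal_per_day,
    neonatal_los_days = neonatal_los_days,
    typical_use_sites = typical_use_sites,
    site_profile = site_profile,
    price_year = price_year, currency = currency
  ), class = "unit_cost_table")
}

#' Voucher awards for one participant
#'
#' Applies the contingency rules to the participant's milestone flags.
#' A missing milestone counts as not achieved. The £200 late-pregnancy
#' voucher requires a verified quit or, in the covid era when allowed, a
#' self-reported quit with a saliva sample; it never depends on the earlier
#' vouchers (unless `late_requires_previous` is set). Milestones listed in
#' `exclude` are treated as issued-but-not-received (e.g. stolen vouchers)
#' and drop out of the total.
#'
#' @param record one participant row (list or single-row data frame)
#' @param schedule a [voucher_schedule()]
#' @param exclude character vector of milestone names whose vouchers are
#'   excluded from costing
#' @return list with `awards` (tibble of milestone, amount) and `total`
#' @export
voucher_awards <- function(record, schedule = voucher_schedule(),
                           exclude = character()) {
  record <- as.list(record)
  is_quit <- function(x) !is.null(x) && !is.na(x) && x == "quit"
  flag <- function(x) !is.null(x) && !is.na(x) && isTRUE(as.logical(x))

  eng <- flag(record$engaged)
  q4 <- is_quit(record$quit_4wk) && (!schedule$quit4_requires_previous || eng)
  q12 <- is_quit(record$quit_12wk) && (!schedule$quit12_requires_previous || q4)
  covid_path <- schedule$covid_selfreport_allowed && flag(record$covid_era) &&
    is_quit(record$quit_late_selfreport) && flag(record$saliva_provided)
  late <- (is_quit(record$quit_late) || covid_path) &&
    (!schedule$late_requires_previous || q12)

  milestones <- c("engagement", "quit_4wk", "quit_12wk", "late_pregnancy")
  met <- c(eng, q4, q12, late)
  amounts <- c(schedule$engagement_amount, schedule$quit4_amount,
               schedule$quit12_amount, schedule$late_amount)
  awards <- tibble::tibble(milestone = milestones[met],
                           amount = amounts[met])
  kept <- !(awards$milestone %in% exclude)
  list(awards = awards,
       total = sum(awards$amount[kept]),
       n_issued = nrow(awards))
}

#' Postage cost for issued and re-sent vouchers
#'
#' @param n_sent number of vouchers issued (each incurs standard postage)
#' @param n_resent_charged number of re-sent vouchers that incurred the
#'   re-send charge (uncharged re-sends cost nothing)
#' @param schedule a [voucher_schedule()]
#' @return cost in pounds
#' @export
postage_cost <- function(n_sent, n_resent_charged,
                         schedule = voucher_schedule()) {
  if (any(c(n_sent, n_resent_charged) < 0)) {
    stop_field("n_sent", "counts must be >= 0")
  }
  n_sent * schedule$postage_per_voucher +
    n_resent_charged * schedule$resend_postage
}

#' Neonatal cost from gestational age at birth
#'
#' Gestational age at birth proxies neonatal care: births before 37 weeks
#' are classed extremely (<28), very (28 to <32) or moderate-to-late
#' (32 to <37) preterm, and costed as the class length of stay times the
#' class per-day cost. Term births (>= 37 weeks) cost zero; a missing
#' gestational age yields a missing cost, which flows to imputation.
#'
#' @param gestational_age_birth_weeks numeric vector (NA allowed)
#' @param unit_costs a [unit_cost_table()]
#' @return numeric vector of costs in pounds
#' @export
neonatal_cost <- function(gestational_age_birth_weeks,
                          unit_costs = unit_cost_table()) {
  g <- gestational_age_birth_weeks
  bad <- !is.na(g) & (g <= 20 | g >= 45)
  if (any(bad)) {
    stop_field("gestational_age_birth_weeks",
               "gestational age must lie in (20, 45) weeks")
  }
  cls <- ifelse(is.na(g), NA_character_,
                ifelse(g >= 37, "term",
                       ifelse(g >= 32, "moderate_late",
                              ifelse(g >= 28, "very", "extremely"))))
  cost <- rep(NA_real_, length(g))
  cost[!is.na(cls) & cls == "term"] <- 0
  for (k in c("moderate_late", "very", "extremely")) {
    sel <- !is.na(cls) & cls == k
    cost[sel] <- unit_costs$neonatal_los_days[[k]] *
      unit_costs$neonatal_per_day[[k]]
  }
  cost
}

#' Cessation support and NRT costs for one participant
#'
#' Adviser contact is costed at the site's pay-grade hourly rate; NRT at
#' the weekly price times prescribed weeks. At sites without individual
#' support-use records ("typical use" sites), missing values are replaced
#' by the configured site profile; elsewhere missing values stay missing.
#'
#' @param record one participant row (list or single-row data frame)
#' @param unit_costs a [unit_cost_table()]
#' @return list with `sss` and `nrt` costs in pounds (possibly NA)
#' @export
support_costs <- function(record, unit_costs = unit_cost_table()) {
  record <- as.list(record)
  grade <- as.character(record$adviser_grade)
  if (!grade %in% names(unit_costs$adviser_rate_per_hour)) {
    stop_field("adviser_grade", paste("unknown grade:", grade))
  }
  rate <- unit_costs$adviser_rate_per_hour[[grade]]
  minutes <- record$sss_contact_minutes
  weeks <- record$nrt_weeks
  typical <- !is.null(record$site) &&
    record$site %in% unit_costs$typical_use_sites
  if (typical) {
    if (is.na(minutes)) minutes <- unit_costs$site_profile$sss_contact_minutes
    if (is.na(weeks)) weeks <- unit_costs$site_profile$nrt_weeks
  }
  list(sss = if (is.na(minutes)) NA_real_ else minutes / 60 * rate,
       nrt = if (is.na(weeks)) NA_real_ else weeks * unit_costs$nrt_cost_per_week)
}

#' Cost every participant in a table
#'
#' Applies the voucher rules, postage, support and neonatal costing to
#' each record, appending per-participant cost columns: `cost_vouchers`,
#' `cost_postage`, `cost_sss`, `cost_nrt`, `cost_intervention` (their sum),
#' `cost_neonatal` and `cost_total`. Control-arm voucher and postage costs
#' are zero by construction. Missing support or neonatal inputs propagate
#' to a missing total (handled downstream by imputation).
#'
#' @param table participant tibble
#' @param schedule a [voucher_schedule()]
#' @param unit_costs a [unit_cost_table()]
#' @return the table with cost columns appended
#' @export
cost_participants <- function(table, schedule = voucher_schedule(),
                              unit_costs = unit_cost_table()) {
  n <- nrow(table)
  # Vectorised application of the same rules as voucher_awards() /
  # support_costs() (agreement is asserted in the test suite).
  quit_of <- function(x) !is.na(x) & x == "quit"
  inc <- table$arm == "incentives"
  eng <- inc & !is.na(table$engaged) & table$engaged
  q4 <- quit_of(table$quit_4wk) &
    (!schedule$quit4_requires_previous | eng) & inc
  q12 <- quit_of(table$quit_12wk) &
    (!schedule$quit12_requires_previous | q4) & inc
  covid_path <- schedule$covid_selfreport_allowed &
    !is.na(table$covid_era) & table$covid_era &
    quit_of(table$quit_late_selfreport) &
    !is.na(table$saliva_provided) & table$saliva_provided
  late <- (quit_of(table$quit_late) | covid_path) &
    (!schedule$late_requires_previous | q12) & inc
  vouchers <- schedule$engagement_amount * eng +
    schedule$quit4_amount * q4 +
    schedule$quit12_amount * q12 +
    schedule$late_amount * late
  n_issued <- eng + q4 + q12 + late

  rate <- unit_costs$adviser_rate_per_hour[as.character(table$adviser_grade)]
  if (anyNA(rate)) stop_field("adviser_grade", "unknown grade")
  minutes <- table$sss_contact_minutes
  weeks <- table$nrt_weeks
  typical <- table$site %in% unit_costs$typical_use_sites
  minutes[typical & is.na(minutes)] <- unit_costs$site_profile$sss_contact_minutes
  weeks[typical & is.na(weeks)] <- unit_costs$site_profile$nrt_weeks
  sss <- minutes / 60 * rate
  nrt <- weeks * unit_costs$nrt_cost_per_week
  postage <- postage_cost(n_issued,
                          ifelse(table$arm == "incentives",
                                 table$n_resent_charged, 0L),
                          schedule)
  neonatal <- neonatal_cost(table$gestational_age_birth_weeks, unit_costs)
  # Miscarriage: no live birth, no neonatal stay.
  neonatal[table$miscarriage] <- 0

  out <- table
  out$cost_vouchers <- vouchers
  out$cost_postage <- postage
  out$cost_sss <- sss
  out$cost_nrt <- nrt
  out$cost_intervention <- vouchers + postage + sss + nrt
  out$cost_neonatal <- neonatal
  out$cost_total <- out$cost_intervention + neonatal
  out
}

#' Per-arm cost breakdown means with standard errors
#'
#' Means are computed over non-missing values per component; the standard
#' error is the sample SD over the square root of the non-missing count.
#'
#' @param table costed participant tibble (see [cost_participants()])
#' @return tibble with one row per arm and component
#' @export
arm_cost_summary <- function(table) {
  comps <- c("cost_vouchers", "cost_postage", "cost_sss", "cost_nrt",
             "cost_intervention", "cost_neonatal", "cost_total")
  stopifnot(all(comps %in% names(table)))
  if (nrow(table) == 0) stop_field("arm", "empty arm: no participants")
  arms <- unique(table$arm)
  if (any(!table$arm %in% c("incentives", "control"))) {
    stop_field("arm", "arms must be 'incentives' or 'control'")
  }
  rows <- list()
  for (a in arms) {
    sub <- table[table$arm == a, ]
    if (nrow(sub) == 0) stop_field("arm", paste("empty arm:", a))
    for (cmp in comps) {
      x <- sub[[cmp]][!is.na(sub[[cmp]])]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = a, component = cmp, n = length(x),
        mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
    }
  }
  dplyr::bind_rows(rows)
}
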