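#' Generate a synthetic trial cohort
#'
#' Draws one participant table with the statistical structure declared in
#' the [cohort_spec()]: milestone quit chain, late-pregnancy voucher-award
#' pathway (verified quit, or covid-era self-report with saliva sample),
#' sustained post-partum quit among late-pregnancy quitters, truncated-normal
#' EQ-5D utilities, quit-status-dependent preterm birth class with a
#' gestational age at birth, cessation-support and NRT resource use, and
#' voucher re-send counts. All values are complete; use
#' [inject_missingness()] to mask variables missing-at-random.
#'
#' Every variable is drawn from a named substream of `spec$seed`, so the
#' table is reproducible and stable under the addition of new variables.
#'
#' @param spec a [cohort_spec()]
#' @return a tibble with one row per participant
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_arm <- c(incentives = spec$n_incentives, control = spec$n_control)
  n <- sum(n_arm)
  arm <- rep(names(n_arm), n_arm)
  seed <- spec$seed

  site <- with_substream(seed, "site",
    sample.int(spec$n_sites, n, replace = TRUE, prob = spec$site_weights))
  covid_era <- with_substream(seed, "covid_era",
    runif(n) < spec$covid_era_frac)
  age <- with_substream(seed, "age",
    round(rtruncnorm_(n, spec$mother_age_mean, spec$mother_age_sd, 16, 45), 1))
  years_smoking <- with_substream(seed, "years_smoking",
    pmin(pmax(round(rnorm(n, 10, 5)), 1), pmax(age - 12, 1)))
  gest_booking <- with_substream(seed, "gest_booking",
    round(runif(n, 8, 23.9), 1))
  miscarriage <- with_substream(seed, "miscarriage",
    runif(n) < spec$miscarriage_prob)

  # Milestone chain: engagement -> 4wk -> 12wk, conditional continuation
  # probabilities back-derived from the marginal targets per arm.
  p_eng <- spec$engage_prob[arm]
  p4 <- spec$quit_prob_4wk[arm] / spec$engage_prob[arm]
  p12 <- spec$quit_prob_12wk[arm] / spec$quit_prob_4wk[arm]
  engaged <- with_substream(seed, "engaged", runif(n) < p_eng)
  quit4 <- engaged & with_substream(seed, "quit4", runif(n) < p4)
  quit12 <- quit4 & with_substream(seed, "quit12", runif(n) < p12)

  # Late-pregnancy verified quit: sticky continuation from the 12-week
  # state, recovery probability among the rest solved to hit the marginal.
  p_late <- spec$quit_prob_late[arm]
  p12m <- spec$quit_prob_12wk[arm]
  p_cont <- spec$late_given_12wk
  p_rec <- pmax(0, (p_late - p_cont * p12m) / (1 - p12m))
  quit_late <- with_substream(seed, "quit_late",
    ifelse(quit12, runif(n) < p_cont, runif(n) < p_rec))

  # Self-report layer on top of the verified status. In the incentives arm
  # the covid-era conditional rate is raised so that the marginal
  # late-voucher issuance matches `late_award_prob`; pre-covid absorbs the
  # remainder so the marginal self-report rate stays on target.
  sr <- selfreport_conditionals(spec)
  sr_cond <- ifelse(covid_era, sr$covid[arm], sr$pre[arm])
  selfreport_extra <- !quit_late &
    with_substream(seed, "selfreport", runif(n) < sr_cond)
  quit_late_selfreport <- quit_late | selfreport_extra

  # Late voucher pathway: verified quit any era; covid-era self-report with
  # a saliva sample. Only meaningful for the incentives arm.
  saliva_provided <- covid_era & quit_late_selfreport
  late_award <- quit_late | (covid_era & selfreport_extra)

  # Sustained 6-month post-partum quit nested in late-pregnancy quitters.
  p_pp_cond <- spec$quit_prob_postpartum[arm] / spec$quit_prob_late[arm]
  quit_pp <- quit_late & with_substream(seed, "quit_pp", runif(n) < p_pp_cond)

  verification <- ifelse(quit_late, ifelse(covid_era, "saliva", "CO"),
                         ifelse(selfreport_extra, "self_report", "CO"))

  # Utilities: truncated normal on the value-set support, per arm and
  # timepoint.
  # Location parameters are moment-matched so the declared means survive
  # truncation to the value-set range.
  lo <- spec$utility_range[1]; hi <- spec$utility_range[2]
  um <- spec$utility_mean
  loc <- apply(um, c(1, 2), truncnorm_location,
               sd = spec$utility_sd, lo = lo, hi = hi)
  u_base <- with_substream(seed, "utility_baseline",
    rtruncnorm_(n, loc["baseline", arm], spec$utility_sd, lo, hi))
  u_late <- with_substream(seed, "utility_late",
    rtruncnorm_(n, loc["late", arm], spec$utility_sd, lo, hi))
  u_pp <- with_substream(seed, "utility_postpartum",
    rtruncnorm_(n, loc["postpartum", arm], spec$utility_sd, lo, hi))

  # Birth outcome: preterm class depends on late-pregnancy smoking status;
  # miscarriage means no live birth and no gestational age.
  classes <- c("extremely", "very", "moderate_late", "term")
  class_lo <- c(extremely = 24, very = 28, moderate_late = 32, term = 37)
  class_hi <- c(extremely = 27.9, very = 31.9, moderate_late = 36.9, term = 41.5)
  pm <- rbind(smoker = spec$preterm_probs$smoker[classes],
              quit = spec$preterm_probs$quit[classes])
  status <- ifelse(quit_late, "quit", "smoker")
  birth_class <- with_substream(seed, "preterm_class", {
    u <- runif(n)
    cum <- t(apply(pm, 1, cumsum))
    idx <- ifelse(status == "quit", 2L, 1L)
    vapply(seq_len(n), function(i) {
      classes[which(u[i] <= cum[idx[i], ])[1]]
    }, character(1))
  })
  gest_birth <- with_substream(seed, "gest_birth",
    round(runif(n, class_lo[birth_class], class_hi[birth_class]), 1))
  gest_birth[miscarriage] <- NA_real_

  nrt_weeks <- with_substream(seed, "nrt_weeks",
    pmin(stats::rpois(n, spec$nrt_weeks_mean[arm]), 12L))
  sss_minutes <- with_substream(seed, "sss_minutes",
    round(rgamma(n, shape = 2, scale = spec$sss_minutes_mean[arm] / 2)))
  # Adviser grade is a site attribute: first four sites grade 5, rest 6.
  adviser_grade <- ifelse(site <= 4, 5L, 6L)

  # Re-send counts per issued voucher (incentives arm only; costing turns
  # these into postage).
  n_awards <- ifelse(arm == "incentives",
                     engaged + (quit4 & engaged) + (quit12 & quit4) + late_award,
                     0L)
  n_resent <- with_substream(seed, "resend",
    rbinom(n, n_awards, spec$resend_prob))
  n_resent_charged <- with_substream(seed, "resend_charged",
    rbinom(n, n_resent, spec$resend_charged_frac))

  tri <- function(x) ifelse(x, "quit", "smoker")
  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    site = as.integer(site),
    age_years = age,
    years_smoking = as.numeric(years_smoking),
    gestation_at_booking_weeks = gest_booking,
    covid_era = covid_era,
    engaged = engaged,
    quit_4wk = tri(quit4),
    quit_12wk = tri(quit12),
    quit_late = tri(quit_late),
    quit_late_selfreport = tri(quit_late_selfreport),
    quit_postpartum = tri(quit_pp),
    saliva_provided = saliva_provided,
    late_award = late_award,
    verification = verification,
    utility_baseline = u_base,
    utility_late = u_late,
    utility_postpartum = u_pp,
    t_late_years = spec$t_late_years,
    t_postpartum_years = spec$t_postpartum_years,
    nrt_weeks = as.integer(nrt_weeks),
    sss_contact_minutes = as.numeric(sss_minutes),
    adviser_grade = adviser_grade,
    gestational_age_birth_weeks = gest_birth,
    miscarriage = miscarriage,
    withdrew = FALSE,
    n_resent = as.integer(n_resent),
    n_resent_charged = as.integer(n_resent_charged)
  )
}

# Conditional self-report probabilities among non-verified participants,
# by era and arm, derived from the marginal self-report and voucher-award
# targets.
selfreport_conditionals <- function(spec) {
  arms <- c("incentives", "control")
  p_late <- spec$quit_prob_late[arms]
  p_sr <- spec$quit_prob_late_selfreport[arms]
  f <- spec$covid_era_frac
  sr_cond <- (p_sr - p_late) / (1 - p_late)
  covid <- sr_cond
  pre <- sr_cond
  # Incentives arm: covid-era self-reporters (with saliva) also receive the
  # late voucher, so their conditional rate is pinned by the issuance target.
  if (f > 0) {
    need <- (spec$late_award_prob - p_late[["incentives"]]) /
      (f * (1 - p_late[["incentives"]]))
    need <- min(max(need, 0), 1)
    covid[["incentives"]] <- need
    pre[["incentives"]] <-
      min(max((sr_cond[["incentives"]] - f * need) / (1 - f), 0), 1)
  }
  list(covid = covid, pre = pre)
}

#' Mask table columns missing-at-random
#'
#' Sets a target proportion of each named column to `NA`, with the
#' missingness probability a logistic function of the driver columns
#' (default: miscarriage and trial site) and never of the masked value
#' itself, i.e. missing-at-random. The intercept of each logistic tilt is
#' solved so the marginal missingness matches the target rate.
#'
#' Columns listed in `nested` are masked only where their parent column is
#' already missing (e.g. cessation-support costs are a subset of the
#' missing NRT records in the trial's missingness table); the target rate
#' remains the marginal one.
#'
#' @param table participant tibble from [generate_cohort()]
#' @param missing_rates named vector of target marginal missing proportions
#' @param drivers character vector of driver column names present in
#'   `table`
#' @param nested named character vector mapping a column to the parent
#'   column within whose missing rows it must lie
#' @param seed integer seed (masking uses substream "missingness")
#' @param tilt strength of the logistic dependence on the drivers
#' @return the table with `NA`s injected
#' @export
inject_missingness <- function(table, missing_rates,
                               drivers = c("miscarriage", "site"),
                               nested = c(sss_contact_minutes = "nrt_weeks"),
                               seed = 1L, tilt = 1) {
  if (!is_prob(missing_rates)) {
    stop_field("missing_rates", "probabilities must lie in [0, 1]")
  }
  missing_drivers <- setdiff(drivers, names(table))
  if (length(missing_drivers)) {
    stop_field("drivers", paste("unknown driver column:",
                                paste(missing_drivers, collapse = ", ")))
  }
  unknown <- setdiff(names(missing_rates), names(table))
  if (length(unknown)) {
    stop_field("missing_rates", paste("unknown column:",
                                      paste(unknown, collapse = ", ")))
  }
  n <- nrow(table)
  # Linear predictor from drivers only (MAR): centred numeric codes.
  lp <- rep(0, n)
  for (d in drivers) {
    v <- as.numeric(table[[d]])
    if (stats::sd(v) > 0) lp <- lp + tilt * (v - mean(v)) / stats::sd(v)
  }

  # Mask parents before nested children so eligibility is known.
  cols <- names(missing_rates)
  parents <- unname(nested[cols[cols %in% names(nested)]])
  ordering <- c(setdiff(cols, names(nested)), intersect(cols, names(nested)))

  out <- table
  for (col in ordering) {
    rate <- missing_rates[[col]]
    if (rate == 0) next
    eligible <- rep(TRUE, n)
    if (col %in% names(nested)) {
      parent <- nested[[col]]
      if (parent %in% names(out)) eligible <- is.na(out[[parent]])
    }
    mask <- with_substream(seed, paste0("missingness/", col), {
      if (rate >= 1) {
        rep(TRUE, n)
      } else if (!any(eligible)) {
        rep(FALSE, n)
      } else {
        lpe <- lp[eligible]
        target <- min(rate * n / sum(eligible), 0.999)
        a <- uniroot(function(a) mean(plogis(a + lpe)) - target,
                     c(-30, 30))$root
        m <- rep(FALSE, n)
        m[eligible] <- runif(sum(eligible)) < plogis(a + lpe)
        m
      }
    })
    out[[col]][mask] <- NA
  }
  out
}

#' Generate a cohort and mask it per its missingness targets
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [inject_missingness()] using the spec's `missing_rates` and seed.
#'
#' @param spec a [cohort_spec()]
#' @return a masked participant tibble
#' @export
simulate_trial <- function(spec) {
  inject_missingness(generate_cohort(spec), spec$missing_rates,
                     seed = spec$seed)
}
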