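#' Specification of a synthetic trial cohort
#'
#' Defines the statistical structure of a two-arm randomized trial of
#' contingent financial incentives for smoking cessation in pregnancy:
#' arm sizes, site mix, the milestone quit process (engagement with stop
#' smoking services, 4-week, 12-week and late-pregnancy verified quits,
#' 6-month post-partum sustained quit), EQ-5D utility means, preterm-birth
#' probabilities by smoking status, and per-variable missingness targets.
#'
#' Defaults reproduce the published marginal structure of the trial the
#' package emulates: 471/470 participants across seven sites, verified
#' late-pregnancy quit rates 0.268 (incentives) and 0.123 (control),
#' self-reported quit rates 0.359/0.185, post-partum sustained quit rates
#' 0.079/0.051, voucher-stage issuance proportions 71.4%, 36.2%, 29.2% and
#' 31.8% in the incentives arm, and missingness proportions matching the
#' trial's missing-data table. Quantities the trial did not report (site
#' weights, utility SDs, preterm class probabilities) are documented
#' synthetic defaults.
#'
#' Milestones are generated as a chain (engagement, then 4-week quit among
#' engagers, then 12-week quit among 4-week quitters) with continuation
#' probabilities derived from the marginal targets, so generated 12-week
#' quitters are always a subset of engagers.
#'
#' @param n_incentives,n_control arm sizes
#' @param n_sites number of recruitment sites
#' @param site_weights probability vector over sites (sums to 1)
#' @param engage_prob per-arm probability of engaging with cessation
#'   services and setting a quit date, `c(incentives, control)`
#' @param quit_prob_4wk,quit_prob_12wk per-arm marginal probabilities of
#'   verified quit at 4 and 12 weeks post quit date (nested within
#'   engagement)
#' @param quit_prob_late per-arm verified late-pregnancy quit probability
#' @param quit_prob_late_selfreport per-arm self-reported late-pregnancy
#'   quit probability (at least the verified rate)
#' @param late_award_prob incentives-arm marginal probability of receiving
#'   the late-pregnancy voucher (verified quit, or covid-era self-report
#'   with a saliva sample)
#' @param quit_prob_postpartum per-arm sustained quit probability at 6
#'   months post-partum (must not exceed `quit_prob_late`)
#' @param late_given_12wk probability a verified 12-week quitter is still
#'   quit at late pregnancy
#' @param utility_mean 3 x 2 matrix of EQ-5D utility means, rows baseline /
#'   late pregnancy / post-partum, columns incentives / control
#' @param utility_sd common utility standard deviation (truncated-normal
#'   draws on the value-set range)
#' @param utility_range support of the utility value set
#' @param preterm_probs list with elements `smoker` and `quit`, each a
#'   probability vector over birth classes `extremely`, `very`,
#'   `moderate_late`, `term` (sums to 1)
#' @param miscarriage_prob probability of miscarriage (no live birth)
#' @param covid_era_frac fraction of participants whose primary outcome was
#'   collected after 16 March 2020 (self-report verification pathway)
#' @param missing_rates named vector of target marginal missingness
#'   proportions per column
#' @param t_late_years,t_postpartum_years follow-up interval lengths in
#'   years (baseline to late pregnancy; late pregnancy to 6 months
#'   post-partum)
#' @param nrt_weeks_mean per-arm mean weeks of nicotine replacement therapy
#' @param sss_minutes_mean per-arm mean minutes of cessation-adviser contact
#' @param resend_prob probability an issued voucher needs re-sending
#' @param resend_charged_frac fraction of re-sent vouchers incurring the
#'   re-send postage charge
#' @param mother_age_mean,mother_age_sd baseline age distribution (years)
#' @param seed master integer seed; every variable draws from a named
#'   substream of it
#'
#' @return an object of class `cohort_spec`
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
cohort_spec <- function(n_incentives = 471L,
                        n_control = 470L,
                        n_sites = 7L,
                        site_weights = rep(1 / n_sites, n_sites),
                        engage_prob = c(incentives = 0.714, control = 0.60),
                        quit_prob_4wk = c(incentives = 0.362, control = 0.20),
                        quit_prob_12wk = c(incentives = 0.292, control = 0.15),
                        quit_prob_late = c(incentives = 0.268, control = 0.123),
                        quit_prob_late_selfreport = c(incentives = 0.359, control = 0.185),
                        late_award_prob = 0.318,
                        quit_prob_postpartum = c(incentives = 0.079, control = 0.051),
                        late_given_12wk = 0.75,
                        utility_mean = matrix(c(0.680, 0.685, 0.690,
                                                0.680, 0.670, 0.680),
                                              nrow = 3, ncol = 2,
                                              dimnames = list(
                                                c("baseline", "late", "postpartum"),
                                                c("incentives", "control"))),
                        utility_sd = 0.25,
                        utility_range = c(-0.594, 1),
                        preterm_probs = list(
                          smoker = c(extremely = 0.004, very = 0.010,
                                     moderate_late = 0.055, term = 0.931),
                          quit = c(extremely = 0.002, very = 0.005,
                                   moderate_late = 0.035, term = 0.958)),
                        miscarriage_prob = 0.019,
                        covid_era_frac = 0.30,
                        missing_rates = c(sss_contact_minutes = 0.10,
                                          nrt_weeks = 0.12,
                                          quit_late = 0.10,
                                          quit_postpartum = 0.20,
                                          utility_baseline = 0.002,
                                          utility_late = 0.23,
                                          utility_postpartum = 0.28),
                        t_late_years = 0.5,
                        t_postpartum_years = 0.65,
                        nrt_weeks_mean = c(incentives = 3.9, control = 3.0),
                        sss_minutes_mean = c(incentives = 71, control = 56),
                        resend_prob = 87 / 793,
                        resend_charged_frac = 59 / 87,
                        mother_age_mean = 28,
                        mother_age_sd = 5.5,
                        seed = 1L) {
  spec <- list(
    n_incentives = as.integer(n_incentives), n_control = as.integer(n_control),
    n_sites = as.integer(n_sites), site_weights = site_weights,
    engage_prob = engage_prob, quit_prob_4wk = quit_prob_4wk,
    quit_prob_12wk = quit_prob_12wk, quit_prob_late = quit_prob_late,
    quit_prob_late_selfreport = quit_prob_late_selfreport,
    late_award_prob = late_award_prob,
    quit_prob_postpartum = quit_prob_postpartum,
    late_given_12wk = late_given_12wk,
    utility_mean = utility_mean, utility_sd = utility_sd,
    utility_range = utility_range, preterm_probs = preterm_probs,
    miscarriage_prob = miscarriage_prob, covid_era_frac = covid_era_frac,
    missing_rates = missing_rates,
    t_late_years = t_late_years, t_postpartum_years = t_postpartum_years,
    nrt_weeks_mean = nrt_weeks_mean, sss_minutes_mean = sss_minutes_mean,
    resend_prob = resend_prob, resend_charged_frac = resend_charged_frac,
    mother_age_mean = mother_age_mean, mother_age_sd = mother_age_sd,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks every probability lies in \[0, 1\], `site_weights` and each
#' preterm-class vector sum to 1, milestone marginals are compatible with
#' the nesting (engagement contains 4-week quit contains 12-week quit) and
#' the post-partum sustained quit rate does not exceed the late-pregnancy
#' rate in either arm. Errors name the offending field.
#'
#' @param spec a `cohort_spec`
#' @return `spec`, invisibly, if valid
#' @export
validate_cohort_spec <- function(spec) {
  for (f in c("engage_prob", "quit_prob_4wk", "quit_prob_12wk",
              "quit_prob_late", "quit_prob_late_selfreport",
              "quit_prob_postpartum", "miscarriage_prob", "covid_era_frac",
              "late_award_prob", "late_given_12wk", "resend_prob",
              "resend_charged_frac")) {
    if (!is_prob(spec[[f]])) stop_field(f, "probabilities must lie in [0, 1]")
  }
  if (!is_prob(spec$missing_rates)) {
    stop_field("missing_rates", "probabilities must lie in [0, 1]")
  }
  if (!is_prob(spec$site_weights) ||
      abs(sum(spec$site_weights) - 1) > 1e-9 ||
      length(spec$site_weights) != spec$n_sites) {
    stop_field("site_weights",
               "must be a probability vector over sites summing to 1")
  }
  for (cls in names(spec$preterm_probs)) {
    p <- spec$preterm_probs[[cls]]
    if (!is_prob(p) || abs(sum(p) - 1) > 1e-9) {
      stop_field("preterm_probs", sprintf("class '%s' must sum to 1", cls))
    }
  }
  if (any(spec$quit_prob_postpartum > spec$quit_prob_late + 1e-12)) {
    stop_field("quit_prob_postpartum",
               "must not exceed quit_prob_late within each arm")
  }
  if (any(spec$quit_prob_4wk > spec$engage_prob + 1e-12) ||
      any(spec$quit_prob_12wk > spec$quit_prob_4wk + 1e-12)) {
    stop_field("quit_prob_4wk",
               "milestone marginals must be nested: engagement >= 4wk >= 12wk")
  }
  if (any(spec$quit_prob_late_selfreport < spec$quit_prob_late - 1e-12)) {
    stop_field("quit_prob_late_selfreport",
               "self-reported quit rate cannot be below the verified rate")
  }
  if (spec$n_incentives < 1L || spec$n_control < 1L) {
    stop_field("n_incentives", "arm sizes must be positive")
  }
  invisible(spec)
}
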