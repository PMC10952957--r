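#' Lifetime mother-infant model parameters
#'
#' Parameter set for the lifetime cost-utility model: a pregnancy decision
#' tree feeding linked Markov cohorts for the mother (to age 100) and the
#' infant (childhood to 15, then adulthood to 100), with annual cycles and
#' 3.5% discounting of costs and QALYs.
#'
#' Trial-derived inputs (arm quit rates, intervention costs, the 1-year
#' relapse rate) carry the published means and standard errors. The
#' remaining state lists, morbidity/mortality rates, state costs and
#' utilities belong to an external published model whose numeric internals
#' are not reproduced here: the defaults below are SYNTHETIC, chosen to
#' satisfy the qualitative orderings the model structure relies on —
#' quitter utility at or above smoker utility, quitter mortality at or
#' below smoker mortality, non-negative smoking-attributable costs — so
#' absolute lifetime magnitudes are illustrative, while structure,
#' adjustments and directional results are meaningful.
#'
#' @param cohort_size trial cohort size feeding the tree's expected counts
#' @param mother_age mother's age at pregnancy (years)
#' @param max_age horizon age for both cohorts
#' @param discount_rate annual discount rate for costs and QALYs
#' @param wtp_reference willingness-to-pay threshold (pounds/QALY)
#' @param quit_rate,quit_rate_se per-arm late-pregnancy quit rates
#' @param intervention_cost,intervention_cost_se per-arm intervention costs
#' @param relapse_1yr,relapse_1yr_se probability a late-pregnancy quitter
#'   has relapsed by one year post-partum
#' @param annual_relapse annual relapse probability after the first year
#' @param background_quit annual background quit probability among smokers
#' @param pregnancy_outcome_probs 2 x 3 matrix, rows `quit`/`smoker`,
#'   columns `normal`/`adverse_live`/`loss`; each row sums to 1
#' @param pregnancy_outcome_cost infant-side cost by pregnancy outcome
#' @param maternity_cost mother-side delivery-year cost by smoking status
#' @param pregnancy_utility mother utility during the pregnancy year by
#'   status
#' @param mortality_gompertz `c(a, b)` of the baseline annual death rate
#'   `exp(a + b * age)`
#' @param mortality_hr hazard ratios by state (`quitter`, `smoker`,
#'   `nonsmoker`)
#' @param age_bands lower bounds of the age bands for state rewards
#' @param state_costs,state_utilities per-status, per-age-band annual cost
#'   and utility schedules for adults (mother and grown infant)
#' @param child_morbidity_onset annual morbidity onset probability for
#'   children, `c(unexposed, exposed)` to maternal smoking
#' @param child_morbidity_remission annual remission probability
#' @param child_mortality baseline annual child death rate (morbidity
#'   applies `child_morbidity_mort_hr`)
#' @param child_morbidity_mort_hr child mortality hazard ratio with
#'   morbidity
#' @param child_costs,child_utilities annual cost and utility by child
#'   state (`healthy`, `morbidity`)
#' @param adverse_birth_morbidity_p0 probability an adverse live birth
#'   starts childhood in the morbidity state
#' @param uptake_base probability the grown infant takes up smoking at 15
#' @param child_uptake_multiplier relative risk of uptake when the mother
#'   smokes post-partum
#' @param cost_se_frac,utility_se PSA dispersion for the synthetic state
#'   costs (gamma, SE as a fraction of the mean) and utilities (beta)
#' @param half_cycle apply a half-cycle correction to Markov accumulation
#' @return an object of class `lifetime_params`
#' @export
lifetime_params <- function(cohort_size = 944L,
                            mother_age = 28,
                            max_age = 100,
                            discount_rate = 0.035,
                            wtp_reference = 20000,
                            quit_rate = c(incentives = 0.268, control = 0.123),
                            quit_rate_se = c(incentives = 0.020, control = 0.015),
                            intervention_cost = c(incentives = 262, control = 91),
                            intervention_cost_se = c(incentives = 11.7, control = 6.40),
                            relapse_1yr = 0.47,
                            relapse_1yr_se = 0.046,
                            annual_relapse = 0.08,
                            background_quit = 0.03,
                            pregnancy_outcome_probs = rbind(
                              quit = c(normal = 0.870, adverse_live = 0.075,
                                       loss = 0.055),
                              smoker = c(normal = 0.780, adverse_live = 0.105,
                                         loss = 0.115)),
                            pregnancy_outcome_cost = c(normal = 3000,
                                                       adverse_live = 18000,
                                                       loss = 1200),
                            maternity_cost = c(quit = 2800, smoker = 3050),
                            pregnancy_utility = c(quit = 0.73, smoker = 0.70),
                            mortality_gompertz = c(a = -10.5, b = 0.088),
                            mortality_hr = c(quitter = 1.15, smoker = 1.8,
                                             nonsmoker = 1.0),
                            age_bands = c(16, 45, 65, 75),
                            state_costs = list(
                              quitter = c(250, 450, 800, 1200),
                              smoker = c(450, 800, 1400, 2000)),
                            state_utilities = list(
                              quitter = c(0.86, 0.82, 0.77, 0.70),
                              smoker = c(0.80, 0.75, 0.70, 0.62)),
                            child_morbidity_onset = c(unexposed = 0.015,
                                                      exposed = 0.030),
                            child_morbidity_remission = 0.10,
                            child_mortality = 4e-4,
                            child_morbidity_mort_hr = 1.5,
                            child_costs = c(healthy = 60, morbidity = 700),
                            child_utilities = c(healthy = 0.95,
                                                morbidity = 0.88),
                            adverse_birth_morbidity_p0 = 0.25,
                            uptake_base = 0.15,
                            child_uptake_multiplier = 1.9,
                            cost_se_frac = 0.2,
                            utility_se = 0.02,
                            half_cycle = FALSE) {
  p <- list(cohort_size = cohort_size, mother_age = mother_age,
            max_age = max_age, discount_rate = discount_rate,
            wtp_reference = wtp_reference,
            quit_rate = quit_rate, quit_rate_se = quit_rate_se,
            intervention_cost = intervention_cost,
            intervention_cost_se = intervention_cost_se,
            relapse_1yr = relapse_1yr, relapse_1yr_se = relapse_1yr_se,
            annual_relapse = annual_relapse,
            background_quit = background_quit,
            pregnancy_outcome_probs = pregnancy_outcome_probs,
            pregnancy_outcome_cost = pregnancy_outcome_cost,
            maternity_cost = maternity_cost,
            pregnancy_utility = pregnancy_utility,
            mortality_gompertz = mortality_gompertz,
            mortality_hr = mortality_hr,
            age_bands = age_bands,
            state_costs = state_costs, state_utilities = state_utilities,
            child_morbidity_onset = child_morbidity_onset,
            child_morbidity_remission = child_morbidity_remission,
            child_mortality = child_mortality,
            child_morbidity_mort_hr = child_morbidity_mort_hr,
            child_costs = child_costs, child_utilities = child_utilities,
            adverse_birth_morbidity_p0 = adverse_birth_morbidity_p0,
            uptake_base = uptake_base,
            child_uptake_multiplier = child_uptake_multiplier,
            cost_se_frac = cost_se_frac, utility_se = utility_se,
            half_cycle = half_cycle)
  class(p) <- "lifetime_params"
  validate_lifetime_params(p)
  p
}

#' Validate lifetime-model parameters
#'
#' Checks probabilities lie in \[0, 1\], each pregnancy-outcome row sums to
#' 1, the discount rate is non-negative, and every adult status has a cost
#' and utility entry per age band.
#'
#' @param p a `lifetime_params`
#' @return `p` invisibly
#' @export
validate_lifetime_params <- function(p) {
  for (f in c("quit_rate", "relapse_1yr", "annual_relapse",
              "background_quit", "uptake_base",
              "adverse_birth_morbidity_p0")) {
    if (!is_prob(p[[f]])) stop_field(f, "probabilities must lie in [0, 1]")
  }
  if (p$discount_rate < 0) stop_field("discount_rate", "must be >= 0")
  po <- p$pregnancy_outcome_probs
  if (any(po < 0) || any(abs(rowSums(po) - 1) > 1e-9)) {
    stop_field("pregnancy_outcome_probs", "each row must sum to 1")
  }
  nb <- length(p$age_bands)
  for (s in names(p$state_costs)) {
    if (length(p$state_costs[[s]]) != nb ||
        length(p$state_utilities[[s]]) != nb) {
      stop_field("state_costs",
                 "every status needs one cost and utility per age band")
    }
  }
  invisible(p)
}

# Annual death probability at a given age for a given status, capped
# below 1.
mortality_rate <- function(p, age, status) {
  base <- exp(p$mortality_gompertz[["a"]] + p$mortality_gompertz[["b"]] * age)
  pmin(base * p$mortality_hr[[status]], 0.999)
}

# Age-band index for adult reward schedules.
band_index <- function(p, age) {
  findInterval(age, p$age_bands)
}
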