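#' Discount factor
#'
#' `(1 + rate)^(-years)`. Year 0 (the pregnancy year) is undiscounted.
#'
#' @param years_from_start non-negative years from model start
#' @param rate annual discount rate (> -1)
#' @return discount factor(s)
#' @export
discount_factor <- function(years_from_start, rate) {
  if (any(years_from_start < 0)) stop_field("years_from_start", "must be >= 0")
  if (rate <= -1) stop_field("rate", "must exceed -1")
  (1 + rate)^(-years_from_start)
}

#' Extrapolate a 6-month post-partum relapse rate to one year
#'
#' Methods: `"constant_hazard"` assumes the 6-month relapse probability
#' reflects a constant hazard, giving `1 - (1 - p)^2` at one year;
#' `"passthrough"` returns the rate unchanged; `"fixed"` returns a supplied
#' externally extrapolated value (used to inject a published 1-year figure
#' whose derivation is not reproducible from the 6-month data).
#'
#' @param rate_6mo 6-month relapse probability
#' @param method one of `"constant_hazard"`, `"passthrough"`, `"fixed"`
#' @param fixed_value value returned under `method = "fixed"`
#' @return 1-year relapse probability
#' @export
extrapolate_relapse <- function(rate_6mo, method = "constant_hazard",
                                fixed_value = NULL) {
  if (!is_prob(rate_6mo)) stop_field("rate_6mo", "must lie in [0, 1]")
  switch(method,
         constant_hazard = 1 - (1 - rate_6mo)^2,
         passthrough = rate_6mo,
         fixed = {
           if (is.null(fixed_value)) stop_field("fixed_value", "required")
           fixed_value
         },
         stop_field("method", paste("unknown method:", method)))
}

#' Run a Markov cohort section
#'
#' Generic annual-cycle cohort engine. The transition matrix, state costs
#' and state utilities may vary by cycle (supplied as functions of the
#' cycle index). Occupancy mass is conserved every cycle; any state named
#' `"dead"` must be absorbing. Discounting is applied at
#' `t = t0 + cycle - 1` years from model start; with `half_cycle = TRUE`
#' rewards are credited as the mean of entry and exit occupancy.
#'
#' @param init named occupancy vector at entry
#' @param n_cycles number of annual cycles
#' @param transition function(cycle) returning a row-stochastic matrix
#' @param cost,utility functions(cycle) returning per-state annual rewards
#' @param discount_rate annual discount rate
#' @param t0 years from model start of the first cycle's rewards
#' @param half_cycle apply half-cycle correction
#' @return list with `trace` (matrix, cycles+1 rows), `cost`, `qaly`
#'   (discounted totals), `life_years` (undiscounted)
#' @export
run_markov <- function(init, n_cycles, transition, cost, utility,
                       discount_rate = 0.035, t0 = 1, half_cycle = FALSE) {
  states <- names(init)
  occ <- init
  trace <- matrix(NA_real_, nrow = n_cycles + 1, ncol = length(states),
                  dimnames = list(NULL, states))
  trace[1, ] <- occ
  total_cost <- 0; total_qaly <- 0; life_years <- 0
  mass <- sum(init)
  for (cyc in seq_len(n_cycles)) {
    P <- transition(cyc)
    check_transition(P, states)
    new_occ <- drop(occ %*% P)
    if (abs(sum(new_occ) - mass) > 1e-8 * max(mass, 1)) {
      stop("cohort mass not conserved at cycle ", cyc)
    }
    payload <- if (half_cycle) (occ + new_occ) / 2 else new_occ
    df <- discount_factor(t0 + cyc - 1, discount_rate)
    total_cost <- total_cost + sum(payload * cost(cyc)) * df
    total_qaly <- total_qaly + sum(payload * utility(cyc)) * df
    alive <- setdiff(states, "dead")
    life_years <- life_years + sum(payload[alive])
    occ <- new_occ
    trace[cyc + 1, ] <- occ
  }
  list(trace = trace, cost = total_cost, qaly = total_qaly,
       life_years = life_years)
}

check_transition <- function(P, states) {
  if (any(P < -1e-12)) stop("negative transition probability")
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  if ("dead" %in% states) {
    d <- which(states == "dead")
    if (abs(P[d, d] - 1) > 1e-12) stop("death must be absorbing")
  }
  invisible(P)
}

#' Pregnancy decision tree for one arm
#'
#' Expected per-mother outcomes of the pregnancy year: the arm quit rate
#' splits the cohort into quitters and continuing smokers, each with its
#' own distribution over birth outcomes (normal, adverse live birth,
#' adverse pregnancy outcome/loss). The intervention cost is charged here,
#' once, undiscounted (year 0). Mother-side costs and QALYs cover the
#' delivery year; infant-side outcome costs are reported separately along
#' with the expected cohort counts of adverse outcomes.
#'
#' @param params a [lifetime_params()]
#' @param arm `"incentives"` or `"control"`
#' @return list with `mother_cost`, `mother_qaly`, `infant_cost`,
#'   `quit_rate`, `p_live_birth`, `p_adverse_live`, `adverse_live_births`
#'   and `adverse_pregnancy_outcomes` (expected cohort counts)
#' @export
run_pregnancy_tree <- function(params, arm) {
  q <- params$quit_rate[[arm]]
  po <- params$pregnancy_outcome_probs
  mix <- q * po["quit", ] + (1 - q) * po["smoker", ]
  mother_cost <- params$intervention_cost[[arm]] +
    q * params$maternity_cost[["quit"]] +
    (1 - q) * params$maternity_cost[["smoker"]]
  mother_qaly <- q * params$pregnancy_utility[["quit"]] +
    (1 - q) * params$pregnancy_utility[["smoker"]]
  infant_cost <- sum(mix * params$pregnancy_outcome_cost)
  list(mother_cost = mother_cost,
       mother_qaly = mother_qaly,
       infant_cost = infant_cost,
       quit_rate = q,
       p_live_birth = mix[["normal"]] + mix[["adverse_live"]],
       p_adverse_live = mix[["adverse_live"]],
       adverse_live_births = params$cohort_size * mix[["adverse_live"]],
       adverse_pregnancy_outcomes =
         params$cohort_size * (mix[["adverse_live"]] + mix[["loss"]]))
}

# Mother Markov section: quitter/smoker/dead from the year after delivery
# to max_age. First-cycle relapse uses the 1-year post-partum relapse
# rate; later cycles the long-run annual relapse; smokers quit at the
# background rate.
mother_section <- function(params, arm) {
  q0 <- params$quit_rate[[arm]]
  init <- c(quitter = q0, smoker = 1 - q0, dead = 0)
  n_cycles <- params$max_age - params$mother_age
  transition <- function(cyc) {
    age <- params$mother_age + cyc
    r <- if (cyc == 1) params$relapse_1yr else params$annual_relapse
    b <- params$background_quit
    mq <- mortality_rate(params, age, "quitter")
    ms <- mortality_rate(params, age, "smoker")
    rbind(quitter = c((1 - mq) * (1 - r), (1 - mq) * r, mq),
          smoker = c((1 - ms) * b, (1 - ms) * (1 - b), ms),
          dead = c(0, 0, 1))
  }
  reward <- function(tab) function(cyc) {
    bi <- band_index(params, params$mother_age + cyc)
    c(quitter = tab$quitter[bi], smoker = tab$smoker[bi], dead = 0)
  }
  run_markov(init, n_cycles, transition,
             cost = reward(params$state_costs),
             utility = reward(params$state_utilities),
             discount_rate = params$discount_rate,
             t0 = 1, half_cycle = params$half_cycle)
}

# Proportion of mothers smoking at one year post-partum (exposure of the
# child); from the arm quit rate and first-year relapse.
maternal_exposure <- function(params, arm) {
  q0 <- params$quit_rate[[arm]]
  1 - q0 * (1 - params$relapse_1yr)
}

# Infant childhood section: healthy/morbidity/dead from birth to 15.
# Adverse live births start partly in the morbidity state; morbidity
# onset is raised by exposure to maternal smoking.
infant_childhood_section <- function(params, arm, tree) {
  exposure <- maternal_exposure(params, arm)
  onset <- exposure * params$child_morbidity_onset[["exposed"]] +
    (1 - exposure) * params$child_morbidity_onset[["unexposed"]]
  p_live <- tree$p_live_birth
  p_adv <- tree$p_adverse_live
  m0 <- p_adv * params$adverse_birth_morbidity_p0
  init <- c(healthy = p_live - m0, morbidity = m0, dead = 1 - p_live)
  rem <- params$child_morbidity_remission
  mc <- params$child_mortality
  mm <- min(mc * params$child_morbidity_mort_hr, 1)
  transition <- function(cyc) {
    rbind(healthy = c((1 - mc) * (1 - onset), (1 - mc) * onset, mc),
          morbidity = c((1 - mm) * rem, (1 - mm) * (1 - rem), mm),
          dead = c(0, 0, 1))
  }
  run_markov(init, 15, transition,
             cost = function(cyc) c(params$child_costs, dead = 0),
             utility = function(cyc) c(params$child_utilities, dead = 0),
             discount_rate = params$discount_rate,
             t0 = 1, half_cycle = params$half_cycle)
}

# Infant adulthood section: smoking uptake at 15 (raised when the mother
# smokes), then smoker/nonsmoker/dead to max_age. Cycle t covers age
# 15 + t, discounted from the model start.
infant_adulthood_section <- function(params, arm, childhood) {
  exposure <- maternal_exposure(params, arm)
  uptake <- min(params$uptake_base *
                  (exposure * params$child_uptake_multiplier +
                     (1 - exposure)), 1)
  final <- childhood$trace[nrow(childhood$trace), ]
  alive <- final[["healthy"]] + final[["morbidity"]]
  init <- c(smoker = alive * uptake, nonsmoker = alive * (1 - uptake),
            dead = final[["dead"]])
  n_cycles <- params$max_age - 15
  b <- params$background_quit
  r <- params$annual_relapse / 4  # adult ex-smoker relapse, modest
  transition <- function(cyc) {
    age <- 15 + cyc
    ms <- mortality_rate(params, age, "smoker")
    mn <- mortality_rate(params, age, "nonsmoker")
    rbind(smoker = c((1 - ms) * (1 - b), (1 - ms) * b, ms),
          nonsmoker = c((1 - mn) * r, (1 - mn) * (1 - r), mn),
          dead = c(0, 0, 1))
  }
  reward <- function(tab) function(cyc) {
    bi <- max(band_index(params, 15 + cyc), 1)
    c(smoker = tab$smoker[bi], nonsmoker = tab$quitter[bi], dead = 0)
  }
  run_markov(init, n_cycles, transition,
             cost = reward(params$state_costs),
             utility = reward(params$state_utilities),
             discount_rate = params$discount_rate,
             t0 = 16, half_cycle = params$half_cycle)
}

#' Run the lifetime model for one arm
#'
#' Pregnancy decision tree plus the mother and infant Markov sections,
#' returning discounted per-mother costs and QALYs for each reporting
#' scenario: maternal end of pregnancy, maternal lifetime, infant end of
#' pregnancy (costs and adverse-outcome counts), infant end of childhood
#' (cumulative from birth) and infant adulthood (cumulative lifetime), and
#' the combined mother-infant lifetime. The intervention cost enters once,
#' in the pregnancy tree.
#'
#' @param params a [lifetime_params()]
#' @param arm `"incentives"` or `"control"`
#' @return list of per-scenario `cost`/`qaly` (per mother), plus
#'   `adverse_live_births` and `adverse_pregnancy_outcomes` cohort counts
#' @export
run_lifetime_arm <- function(params, arm) {
  validate_lifetime_params(params)
  tree <- run_pregnancy_tree(params, arm)
  mother <- mother_section(params, arm)
  child <- infant_childhood_section(params, arm, tree)
  adult <- infant_adulthood_section(params, arm, child)

  maternal_pregnancy <- list(cost = tree$mother_cost, qaly = tree$mother_qaly)
  maternal_lifetime <- list(cost = tree$mother_cost + mother$cost,
                            qaly = tree$mother_qaly + mother$qaly)
  infant_pregnancy <- list(cost = tree$infant_cost, qaly = 0)
  infant_childhood <- list(cost = tree$infant_cost + child$cost,
                           qaly = child$qaly)
  infant_adulthood <- list(cost = infant_childhood$cost + adult$cost,
                           qaly = infant_childhood$qaly + adult$qaly)
  combined <- list(cost = maternal_lifetime$cost + infant_adulthood$cost,
                   qaly = maternal_lifetime$qaly + infant_adulthood$qaly)
  list(maternal_pregnancy = maternal_pregnancy,
       maternal_lifetime = maternal_lifetime,
       infant_pregnancy = infant_pregnancy,
       infant_childhood = infant_childhood,
       infant_adulthood = infant_adulthood,
       combined = combined,
       adverse_live_births = tree$adverse_live_births,
       adverse_pregnancy_outcomes = tree$adverse_pregnancy_outcomes,
       quit_rate = tree$quit_rate)
}

#' Deterministic incremental lifetime results for both arms
#'
#' Runs [run_lifetime_arm()] for the incentives and control arms and
#' differences every scenario, attaching the dominance classification
#' (dominant iff the incremental cost is negative and the incremental
#' QALY positive).
#'
#' @param params a [lifetime_params()]
#' @return tibble with one row per scenario
#' @export
run_lifetime <- function(params) {
  inc <- run_lifetime_arm(params, "incentives")
  ctl <- run_lifetime_arm(params, "control")
  scen <- c("maternal_pregnancy", "maternal_lifetime", "infant_pregnancy",
            "infant_childhood", "infant_adulthood", "combined")
  rows <- lapply(scen, function(s) {
    dc <- inc[[s]]$cost - ctl[[s]]$cost
    de <- inc[[s]]$qaly - ctl[[s]]$qaly
    ic <- icer(dc, de)
    tibble::tibble(scenario = s,
                   cost_incentives = inc[[s]]$cost,
                   cost_control = ctl[[s]]$cost,
                   qaly_incentives = inc[[s]]$qaly,
                   qaly_control = ctl[[s]]$qaly,
                   delta_cost = dc, delta_qaly = de,
                   icer = ic$value, icer_label = ic$label)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "adverse_live_births") <-
    c(incentives = inc$adverse_live_births,
      control = ctl$adverse_live_births)
  attr(out, "adverse_pregnancy_outcomes") <-
    c(incentives = inc$adverse_pregnancy_outcomes,
      control = ctl$adverse_pregnancy_outcomes)
  out
}

#' Break-even intervention cost
#'
#' The incentives-arm intervention cost at which the combined
#' mother-infant lifetime incremental cost crosses zero: below it the
#' strategy is dominant (given a positive incremental QALY). Because
#' lifetime health-care offsets of quitting are non-negative under the
#' parameter orderings, such a cost exists; it is located by root-finding
#' over the intervention cost.
#'
#' @param params a [lifetime_params()]
#' @param upper upper bracket for the search (pounds)
#' @return list with `cost` (break-even intervention cost) and
#'   `delta_qaly` at the root
#' @export
break_even_intervention_cost <- function(params, upper = 1e5) {
  f <- function(cost) {
    p <- params
    p$intervention_cost[["incentives"]] <- cost
    res <- run_lifetime(p)
    res$delta_cost[res$scenario == "combined"]
  }
  lo <- f(0)
  if (lo > 0) {
    stop("no break-even intervention cost: combined incremental cost is ",
         "positive even with a free intervention")
  }
  root <- uniroot(f, c(0, upper), tol = 1e-6)
  res0 <- run_lifetime(params)
  list(cost = root$root,
       delta_qaly = res0$delta_qaly[res0$scenario == "combined"])
}
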