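# Method-of-moments PSA draws. A zero/absent SE is a degenerate
# distribution: the mean is returned without touching the RNG stream, so
# an all-degenerate PSA reproduces the deterministic run bit-for-bit.

#' Beta draw by method of moments
#'
#' @param n number of draws
#' @param mean,se mean and standard error of the probability/utility
#' @return draws in (0, 1); the mean itself when `se` is 0
#' @export
draw_beta <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop_field("se", "standard error incompatible with beta support")
  }
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

#' Gamma draw by method of moments
#'
#' @param n number of draws
#' @param mean,se mean and standard error of the cost
#' @return non-negative draws; the mean itself when `se` is 0
#' @export
draw_gamma <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  if (mean <= 0) stop_field("mean", "gamma requires a positive mean")
  shape <- (mean / se)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# One joint draw of the uncertain parameters: trial inputs carry their
# published SEs; synthetic state rewards use the configured dispersion.
draw_psa_params <- function(params) {
  p <- params
  for (a in c("incentives", "control")) {
    p$quit_rate[[a]] <- draw_beta(1, params$quit_rate[[a]],
                                  params$quit_rate_se[[a]])
    p$intervention_cost[[a]] <- draw_gamma(1, params$intervention_cost[[a]],
                                           params$intervention_cost_se[[a]])
  }
  p$relapse_1yr <- draw_beta(1, params$relapse_1yr, params$relapse_1yr_se)
  for (s in names(p$state_costs)) {
    p$state_costs[[s]] <- vapply(params$state_costs[[s]], function(m) {
      draw_gamma(1, m, params$cost_se_frac * m)
    }, numeric(1))
    p$state_utilities[[s]] <- vapply(params$state_utilities[[s]], function(m) {
      draw_beta(1, m, params$utility_se)
    }, numeric(1))
  }
  # Adverse pregnancy probabilities: beta on each non-reference branch,
  # renormalized into the "normal" branch.
  po <- params$pregnancy_outcome_probs
  se_po <- params$utility_se
  for (r in rownames(po)) {
    adv <- draw_beta(1, po[r, "adverse_live"], se_po / 2)
    lss <- draw_beta(1, po[r, "loss"], se_po / 2)
    p$pregnancy_outcome_probs[r, ] <- c(normal = 1 - adv - lss,
                                        adverse_live = adv, loss = lss)
  }
  p
}

#' Probabilistic sensitivity analysis of the lifetime model
#'
#' Draws every uncertain parameter (beta for probabilities and utilities,
#' gamma for costs, both by method of moments from mean/SE pairs) and
#' re-runs the deterministic model per draw. Intervals are 2.5/97.5
#' percentiles; the probability of cost-effectiveness is the fraction of
#' draws with positive net monetary benefit at the reference threshold.
#'
#' @param params a [lifetime_params()]
#' @param n_samples number of PSA draws
#' @param seed integer seed
#' @param scenario which reporting scenario the sample pairs are for
#' @return list with `samples` (per-draw per-arm and incremental cost and
#'   QALY), `summary` (tibble of pooled results for every scenario) and
#'   `prob_ce` at the reference threshold
#' @export
run_psa <- function(params, n_samples = 10000L, seed = 1L,
                    scenario = "combined") {
  draws <- with_substream(seed, "psa", {
    lapply(seq_len(n_samples), function(i) {
      res <- run_lifetime(draw_psa_params(params))
      res[, c("scenario", "cost_incentives", "cost_control",
              "qaly_incentives", "qaly_control", "delta_cost", "delta_qaly")]
    })
  })
  all <- dplyr::bind_rows(draws, .id = "draw")
  sel <- all[all$scenario == scenario, ]
  samples <- tibble::tibble(
    draw = as.integer(sel$draw),
    cost_incentives = sel$cost_incentives,
    cost_control = sel$cost_control,
    qaly_incentives = sel$qaly_incentives,
    qaly_control = sel$qaly_control,
    delta_cost = sel$delta_cost,
    delta_effect = sel$delta_qaly)

  qt <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  summary <- dplyr::bind_rows(lapply(split(all, all$scenario), function(d) {
    ci_c <- qt(d$delta_cost); ci_q <- qt(d$delta_qaly)
    nmb <- params$wtp_reference * d$delta_qaly - d$delta_cost
    ic <- icer(mean(d$delta_cost), mean(d$delta_qaly))
    tibble::tibble(scenario = d$scenario[1],
                   cost_incentives = mean(d$cost_incentives),
                   cost_control = mean(d$cost_control),
                   qaly_incentives = mean(d$qaly_incentives),
                   qaly_control = mean(d$qaly_control),
                   delta_cost = mean(d$delta_cost),
                   delta_cost_lo = ci_c[1], delta_cost_hi = ci_c[2],
                   delta_qaly = mean(d$delta_qaly),
                   delta_qaly_lo = ci_q[1], delta_qaly_hi = ci_q[2],
                   icer = ic$value, icer_label = ic$label,
                   prob_ce = mean(nmb > 0))
  }))
  list(samples = samples, summary = summary,
       prob_ce = summary$prob_ce[summary$scenario == scenario],
       n_samples = n_samples, seed = seed)
}

#' Lifetime sensitivity scenarios
#'
#' Applies the published input substitutions to the base parameters and
#' reruns the deterministic model (optionally with PSA):
#' \describe{
#'   \item{S1a}{gaming-deflated quit rates 0.239 / 0.098 (11% incentives,
#'     20% control)}
#'   \item{S1b}{gaming deflation of 11% in both arms: 0.239 / 0.109}
#'   \item{S2}{self-reported quit rates 0.359 / 0.185}
#'   \item{S3a}{reduced incentive (max £160): intervention cost £131, quit
#'     rates 0.046 / 0.025}
#'   \item{S3b}{increased incentive (max £800): intervention cost £463,
#'     incentives quit rate 0.34}
#'   \item{S4}{trial-derived 1-year relapse rate 0.814 replacing the
#'     model's 0.47}
#' }
#'
#' @param params base [lifetime_params()]
#' @param scenarios subset of `"base"`, `"S1a"`, `"S1b"`, `"S2"`, `"S3a"`,
#'   `"S3b"`, `"S4"`
#' @param n_psa PSA draws per scenario (0 = deterministic only)
#' @param seed integer seed
#' @return tibble of combined-scenario results, one row per scenario
#' @export
run_all_scenarios <- function(params, scenarios = c("base", "S1a", "S1b",
                                                    "S2", "S3a", "S3b", "S4"),
                              n_psa = 0L, seed = 1L) {
  known <- c("base", "S1a", "S1b", "S2", "S3a", "S3b", "S4")
  bad <- setdiff(scenarios, known)
  if (length(bad)) {
    stop_field("scenarios", paste("unknown scenario id:",
                                  paste(bad, collapse = ", ")))
  }
  overlay <- function(sc) {
    p <- params
    switch(sc,
      base = p,
      S1a = {
        p$quit_rate <- c(
          incentives = adjust_for_gaming(params$quit_rate[["incentives"]], 0.11),
          control = adjust_for_gaming(params$quit_rate[["control"]], 0.20))
        p
      },
      S1b = {
        p$quit_rate <- c(
          incentives = adjust_for_gaming(params$quit_rate[["incentives"]], 0.11),
          control = adjust_for_gaming(params$quit_rate[["control"]], 0.11))
        p
      },
      S2 = {
        p$quit_rate <- c(incentives = 0.359, control = 0.185)
        p$quit_rate_se <- c(incentives = 0.022, control = 0.018)
        p
      },
      S3a = {
        p$intervention_cost[["incentives"]] <- 131
        p$intervention_cost_se[["incentives"]] <- 13.265
        p$quit_rate <- c(incentives = 0.046, control = 0.025)
        p$quit_rate_se <- c(incentives = 0.005, control = 0.003)
        p
      },
      S3b = {
        p$intervention_cost[["incentives"]] <- 463
        p$intervention_cost_se[["incentives"]] <- 47.4
        p$quit_rate[["incentives"]] <- 0.34
        p$quit_rate_se[["incentives"]] <- 0.035
        p
      },
      S4 = {
        p$relapse_1yr <- extrapolate_relapse(0, "fixed", fixed_value = 0.814)
        p$relapse_1yr_se <- 0.079
        p
      })
  }
  rows <- lapply(scenarios, function(sc) {
    p <- overlay(sc)
    det <- run_lifetime(p)
    row <- det[det$scenario == "combined", ]
    row$scenario <- sc
    if (n_psa > 0) {
      psa <- run_psa(p, n_samples = n_psa,
                     seed = substream_seed(seed, paste0("scenario/", sc)))
      s <- psa$summary[psa$summary$scenario == "combined", ]
      row$delta_cost_lo <- s$delta_cost_lo
      row$delta_cost_hi <- s$delta_cost_hi
      row$delta_qaly_lo <- s$delta_qaly_lo
      row$delta_qaly_hi <- s$delta_qaly_hi
      row$prob_ce <- s$prob_ce
    }
    row
  })
  dplyr::bind_rows(rows)
}
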