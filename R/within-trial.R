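#' Analysis configuration for the within-trial evaluation
#'
#' Fixed covariate lists follow the trial's analysis plan: cost models
#' adjust for site, baseline age, years of smoking and whether the primary
#' outcome was collected in the covid era; QALY models adjust for site,
#' baseline age, baseline utility, gestational age at booking and covid
#' era. The within-trial horizon is under a year, so no discounting is
#' applied in this module.
#'
#' @param cost_covariates,qaly_covariates,quit_covariates character vectors
#'   of covariate column names
#' @param bootstrap_reps number of non-parametric bootstrap replicates
#' @param n_imputations number of chained-equation imputations
#' @param wtp_grid willingness-to-pay thresholds (pounds per unit effect)
#' @param wtp_reference reference threshold for cost-effectiveness
#'   probabilities
#' @param cost_family `"gamma_log"` (with Gaussian fallback) or
#'   `"gaussian_identity"`
#' @param seed integer seed for bootstrap and imputation substreams
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(cost_covariates = c("site", "age_years",
                                                "years_smoking", "covid_era"),
                            qaly_covariates = c("site", "age_years",
                                                "utility_baseline",
                                                "gestation_at_booking_weeks",
                                                "covid_era"),
                            quit_covariates = character(),
                            bootstrap_reps = 1000L,
                            n_imputations = 20L,
                            wtp_grid = seq(0, 50000, by = 1000),
                            wtp_reference = 20000,
                            cost_family = "gamma_log",
                            seed = 1L) {
  stopifnot(bootstrap_reps >= 1, n_imputations >= 1)
  if (any(diff(wtp_grid) <= 0) || any(wtp_grid < 0)) {
    stop_field("wtp_grid", "must be non-negative and increasing")
  }
  structure(list(cost_covariates = cost_covariates,
                 qaly_covariates = qaly_covariates,
                 quit_covariates = quit_covariates,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 n_imputations = as.integer(n_imputations),
                 wtp_grid = wtp_grid, wtp_reference = wtp_reference,
                 cost_family = cost_family, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Covariate-adjusted difference between arms
#'
#' Fits a generalized linear model of the outcome on arm plus covariates
#' and reports the marginal arm difference by recycled predictions (mean
#' predicted outcome with every participant set to the incentives arm,
#' minus the same under control). With an identity link and no covariates
#' this equals the difference in arm means. Costs default to a gamma/log
#' model, falling back to Gaussian/identity when the outcome contains
#' non-positive values or the gamma fit does not converge; the family
#' actually used is reported. The 95% interval uses a delta-method
#' standard error of the marginal difference.
#'
#' @param table participant tibble, `arm` coded `"incentives"`/`"control"`
#' @param outcome name of the outcome column
#' @param covariates character vector of covariate columns
#' @param family_spec `"gaussian_identity"` or `"gamma_log"`
#' @param want_se compute the delta-method SE and interval (skipped inside
#'   the bootstrap, where only the point estimate is resampled)
#' @return list with `estimate`, `se`, `ci` (length 2), `family_used`,
#'   `converged`, `n`
#' @export
adjusted_difference <- function(table, outcome, covariates = character(),
                                family_spec = "gaussian_identity",
                                want_se = TRUE) {
  dat <- table[!is.na(table[[outcome]]), , drop = FALSE]
  if (nrow(dat) == 0) stop_field("outcome", "no non-missing outcome values")
  dat$.arm <- as.integer(dat$arm == "incentives")
  if ("site" %in% covariates) dat$site <- factor(dat$site)
  rhs <- paste(c(".arm", covariates), collapse = " + ")
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs))

  family_used <- family_spec
  fit <- NULL
  converged <- TRUE
  if (family_spec == "gamma_log") {
    if (all(dat[[outcome]] > 0)) {
      fit <- tryCatch(glm(fml, data = dat, family = Gamma(link = "log")),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || !fit$converged) fit <- NULL
    }
    if (is.null(fit)) {
      family_used <- "gaussian_identity"
      converged <- FALSE  # gamma path did not converge / not applicable
    }
  }
  if (is.null(fit)) {
    fit <- glm(fml, data = dat, family = gaussian())
  }

  # Marginal (recycled-prediction) arm difference; model matrices built
  # once per fit.
  d1 <- dat; d1$.arm <- 1L
  d0 <- dat; d0$.arm <- 0L
  X1 <- model.matrix(fit$formula, d1)
  X0 <- model.matrix(fit$formula, d0)
  marg <- function(beta) {
    mean(fit$family$linkinv(X1 %*% beta)) -
      mean(fit$family$linkinv(X0 %*% beta))
  }
  beta <- coef(fit)
  est <- marg(beta)
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (want_se) {
    # Delta method: numeric gradient of the marginal difference.
    V <- vcov(fit)
    g <- vapply(seq_along(beta), function(j) {
      h <- max(abs(beta[j]), 1) * 1e-6
      bp <- beta; bp[j] <- bp[j] + h
      bm <- beta; bm[j] <- bm[j] - h
      (marg(bp) - marg(bm)) / (2 * h)
    }, numeric(1))
    se <- sqrt(drop(t(g) %*% V %*% g))
    ci <- est + c(-1, 1) * qnorm(0.975) * se
  }
  list(estimate = est, se = se, ci = ci,
       family_used = family_used,
       converged = converged || family_spec != "gamma_log",
       n = nrow(dat))
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies the incremental pair: `dominant` when the intervention saves
#' cost and gains effect, `dominated` when it costs more and loses effect,
#' `undefined` when the effect difference is zero, otherwise `ratio` with
#' value delta_cost / delta_effect. The reported ICER is rounded to the
#' nearest £100 below £10 000 and the nearest £1000 at or above (matching
#' standard two-significant-figure reporting); the raw ratio is always
#' retained.
#'
#' @param delta_cost incremental cost (pounds)
#' @param delta_effect incremental effect (quitters or QALYs)
#' @return list with `label`, `value` (raw ratio or NA), `reported`
#'   (rounded ratio or NA)
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    label <- "undefined"; value <- NA_real_
  } else if (delta_cost < 0 && delta_effect > 0) {
    label <- "dominant"; value <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    label <- "dominated"; value <- NA_real_
  } else {
    label <- "ratio"; value <- delta_cost / delta_effect
  }
  list(label = label, value = value, reported = round_icer(value))
}

#' Reporting rounding for ICERs
#'
#' Nearest £100 below £10 000; nearest £1000 at or above (two significant
#' figures in the typical range).
#'
#' @param x raw ratio (NA passes through)
#' @return rounded value
#' @export
round_icer <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (abs(x) < 10000) round(x / 100) * 100 else round(x / 1000) * 1000
}

#' Flag an inconsistency between printed incrementals and a printed ICER
#'
#' Recomputes the reported (rounded) ratio from the incremental cost and
#' effect and compares it with a published/printed ICER value. Returns
#' `TRUE` when the printed value cannot be reproduced from its printed
#' inputs, which the scenario runner surfaces as a warning rather than
#' silently adopting either number.
#'
#' @param delta_cost,delta_effect printed incrementals
#' @param reported_icer printed ICER value
#' @return logical: `TRUE` if inconsistent
#' @export
icer_consistency_flag <- function(delta_cost, delta_effect, reported_icer) {
  recomputed <- icer(delta_cost, delta_effect)$reported
  if (is.na(recomputed) || is.na(reported_icer)) return(NA)
  !isTRUE(all.equal(recomputed, reported_icer))
}

#' Non-parametric bootstrap of incremental cost and effect
#'
#' Resamples participants with replacement, stratified by arm, and re-runs
#' the covariate-adjusted difference for the cost and effect outcomes on
#' each replicate. Replicates where a fit fails are redrawn (counted in
#' the `retries` attribute). Seed-reproducible via the config seed.
#'
#' @param table analysable participant tibble (post-imputation)
#' @param config an [analysis_config()]
#' @param cost_col,effect_col outcome columns
#' @param effect_covariates covariates for the effect model
#' @return tibble of `delta_cost`, `delta_effect`, one row per replicate,
#'   with attribute `retries`
#' @export
bootstrap_cea <- function(table, config = analysis_config(),
                          cost_col = "cost_total",
                          effect_col = "qaly_late",
                          effect_covariates = config$qaly_covariates) {
  idx_inc <- which(table$arm == "incentives")
  idx_ctl <- which(table$arm == "control")
  reps <- config$bootstrap_reps
  dc <- numeric(reps); de <- numeric(reps)
  retries <- 0L
  with_substream(config$seed, "bootstrap", {
    r <- 1L
    while (r <= reps) {
      take <- c(sample(idx_inc, length(idx_inc), replace = TRUE),
                sample(idx_ctl, length(idx_ctl), replace = TRUE))
      boot <- table[take, , drop = FALSE]
      res <- tryCatch(list(
        cost = adjusted_difference(boot, cost_col, config$cost_covariates,
                                   config$cost_family, want_se = FALSE),
        eff = adjusted_difference(boot, effect_col, effect_covariates,
                                  "gaussian_identity", want_se = FALSE)),
        error = function(e) NULL)
      if (is.null(res)) { retries <- retries + 1L; next }
      dc[r] <- res$cost$estimate
      de[r] <- res$eff$estimate
      r <- r + 1L
    }
  })
  out <- tibble::tibble(delta_cost = dc, delta_effect = de)
  attr(out, "retries") <- retries
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of bootstrap (or PSA)
#' samples with positive net monetary benefit,
#' `lambda * delta_effect - delta_cost > 0`. At `lambda = 0` this reduces
#' to the probability of cost saving.
#'
#' @param samples tibble with `delta_cost`, `delta_effect`
#' @param wtp_grid non-empty numeric vector of thresholds
#' @return tibble with `threshold` and `probability`
#' @export
ceac <- function(samples, wtp_grid) {
  if (length(wtp_grid) == 0) stop_field("wtp_grid", "empty threshold grid")
  if (nrow(samples) < 1) stop_field("samples", "need at least one sample")
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * samples$delta_effect - samples$delta_cost > 0)
  }, numeric(1))
  tibble::tibble(threshold = wtp_grid, probability = prob)
}

#' Deflate a quit rate for suspected gaming
#'
#' Gaming: passing the reward-linked verification while a secondary
#' biochemical check indicates continued smoking. Handled as a
#' proportional deflation: `rate * (1 - fraction)`. Rounding happens only
#' at reporting.
#'
#' @param rate quit rate in \[0, 1\]
#' @param fraction fraction of apparent quits attributed to gaming
#' @return deflated rate
#' @export
adjust_for_gaming <- function(rate, fraction) {
  if (any(fraction < 0 | fraction > 1)) {
    stop_field("fraction", "must lie in [0, 1]")
  }
  rate * (1 - fraction)
}
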