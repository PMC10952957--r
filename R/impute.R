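#' Multiple imputation by chained equations
#'
#' Replaces missing values in the named columns by iterated univariate
#' regression imputation with predictive-mean-matching donors: each
#' incomplete column is regressed on the predictor columns plus the other
#' target columns (current working values), coefficients are perturbed by
#' a draw from their sampling distribution, and each missing entry
#' receives the observed value of one of the `k` donors whose predicted
#' means are closest to its own. Passes cycle over the columns
#' `iterations` times per imputation; `m` completed tables are returned.
#'
#' Imputation is performed at the disaggregated level (resource-use and
#' utility columns), with derived totals recomputed afterwards by the
#' caller. Missingness drivers (miscarriage, site, arm) should be among
#' the predictors so the procedure is congenial with a
#' missing-at-random mechanism.
#'
#' @param table participant tibble with missing values
#' @param target_cols columns to impute (numeric)
#' @param predictor_cols complete columns used as predictors
#' @param m number of imputations
#' @param iterations chained passes per imputation
#' @param k number of predictive-mean-matching donors
#' @param seed integer seed (substream per imputation)
#' @return list of `m` completed tibbles, class `imputation_set`
#' @export
impute_chained <- function(table,
                           target_cols,
                           predictor_cols = c("arm", "site", "age_years",
                                              "miscarriage", "covid_era"),
                           m = 20L, iterations = 10L, k = 5L, seed = 1L) {
  target_cols <- intersect(target_cols, names(table))
  has_na <- vapply(target_cols, function(cl) anyNA(table[[cl]]), logical(1))
  all_na <- vapply(target_cols, function(cl) all(is.na(table[[cl]])),
                   logical(1))
  if (any(all_na)) {
    stop_field("target_cols",
               paste("column(s) entirely missing:",
                     paste(target_cols[all_na], collapse = ", ")))
  }
  need <- target_cols[has_na]
  if (length(need) == 0) {
    out <- replicate(m, table, simplify = FALSE)
    class(out) <- "imputation_set"
    return(out)
  }

  base_X <- impute_design(table, predictor_cols)
  completed <- vector("list", m)
  for (im in seq_len(m)) {
    completed[[im]] <- with_substream(seed, paste0("imputation/", im), {
      work <- table
      # Initialise missing entries from random observed donors.
      for (cl in need) {
        miss <- is.na(work[[cl]])
        obs <- work[[cl]][!miss]
        work[[cl]][miss] <- sample(obs, sum(miss), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (cl in need) {
          miss <- is.na(table[[cl]])
          others <- setdiff(need, cl)
          X <- cbind(base_X,
                     if (length(others))
                       as.matrix(work[, others, drop = FALSE]))
          y <- table[[cl]]
          work[[cl]][miss] <- pmm_draw(y, X, miss, k)
        }
      }
      work
    })
  }
  class(completed) <- "imputation_set"
  completed
}

# Design matrix from mixed-type predictors (factors expanded, logicals
# numeric), without intercept column collinearity issues.
impute_design <- function(table, predictor_cols) {
  d <- table[, predictor_cols, drop = FALSE]
  for (cl in names(d)) {
    if (is.character(d[[cl]])) d[[cl]] <- factor(d[[cl]])
    if (is.logical(d[[cl]])) d[[cl]] <- as.numeric(d[[cl]])
    if (cl == "site") d[[cl]] <- factor(d[[cl]])
  }
  model.matrix(~ ., data = d)
}

# One predictive-mean-matching draw: Bayesian-ish perturbed OLS on the
# observed rows, donors matched on predicted means.
pmm_draw <- function(y, X, miss, k) {
  obs <- !miss & !is.na(y)
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qr_ <- qr(Xo)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(yo) - length(beta), 1)
  sigma2 <- sum(res^2) / df
  XtXi <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  # Perturb coefficients: beta* ~ N(beta, sigma2 (X'X)^-1)
  L <- chol(sigma2 * XtXi)
  beta_star <- beta + drop(t(L) %*% rnorm(length(beta)))
  pred_obs <- drop(Xo %*% beta_star)
  pred_mis <- drop(Xm %*% beta_star)
  vapply(pred_mis, function(p) {
    donors <- order(abs(pred_obs - p))[seq_len(min(k, length(pred_obs)))]
    yo[sample(donors, 1L)]
  }, numeric(1))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; total
#' variance is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance. The interval uses a normal approximation.
#'
#' @param estimates numeric vector of per-imputation point estimates
#' @param ses numeric vector of per-imputation standard errors
#' @return list with `estimate`, `se`, `ci`, `within`, `between`
#' @export
pool_rubin <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses), length(estimates) >= 1)
  m <- length(estimates)
  qbar <- mean(estimates)
  within <- mean(ses^2)
  between <- if (m > 1) var(estimates) else 0
  total <- within + (1 + 1 / m) * between
  se <- sqrt(total)
  list(estimate = qbar, se = se,
       ci = qbar + c(-1, 1) * qnorm(0.975) * se,
       within = within, between = between)
}
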