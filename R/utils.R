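#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rgamma rbeta qnorm pnorm dnorm plogis
#'   qlogis sd uniroot glm gaussian Gamma coef vcov predict quantile var lm
#'   complete.cases as.formula binomial setNames model.matrix na.omit median
#' @importFrom utils read.csv write.csv head packageVersion
NULL

# Deterministic 32-bit string hash (FNV-1a) used to derive named RNG
# substreams from a single master seed, so adding a variable to the
# generator never perturbs the draws of existing variables.
hash32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' Derive a named RNG substream seed from a master seed
#'
#' All stochastic components draw from substreams keyed by a label, so the
#' same master seed yields the same values for a given variable regardless
#' of what else is simulated.
#'
#' @param seed master integer seed
#' @param stream character label of the substream
#' @return an integer seed below 2^31
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  as.integer((as.numeric(seed) + hash32(stream)) %% .Machine$integer.max)
}

# Evaluate `expr` under a named substream without disturbing the caller's
# RNG state.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

#' Round money to pennies (banker's rounding)
#'
#' Internal arithmetic is carried in full double precision; this is the
#' reporting rounding only. R's `round()` implements half-even.
#'
#' @param x numeric amount in pounds
#' @return amount rounded to 2 decimal places
#' @export
round_pence <- function(x) round(x, 2)

# Truncated-normal sampler on [lo, hi] by inverse-CDF; vectorised over n.
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# Mean of a truncated normal TN(mu, sd, [lo, hi]).
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter such that the truncated-normal mean equals `target`;
# used so declared utility means survive truncation to the value-set range.
truncnorm_location <- function(target, sd, lo, hi) {
  vapply(target, function(m) {
    uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - m,
            c(lo - 4 * sd, hi + 4 * sd))$root
  }, numeric(1))
}

is_prob <- function(p) is.numeric(p) && all(!is.na(p)) && all(p >= 0) && all(p <= 1)

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
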