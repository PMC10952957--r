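# Shared fixtures, built in code at test time.

# Small cohort for fast pipeline tests.
small_spec <- function(seed = 11L, ...) {
  cohort_spec(n_incentives = 160L, n_control = 160L, seed = seed, ...)
}

# One fully specified participant record for unit tests of per-record
# operations.
participant_record <- function(engaged = TRUE, quit_4wk = "quit",
                               quit_12wk = "quit", quit_late = "quit",
                               quit_late_selfreport = quit_late,
                               covid_era = FALSE, saliva_provided = FALSE,
                               site = 1L, adviser_grade = 5L,
                               sss_contact_minutes = 60,
                               nrt_weeks = 4L, arm = "incentives") {
  list(arm = arm, engaged = engaged, quit_4wk = quit_4wk,
       quit_12wk = quit_12wk, quit_late = quit_late,
       quit_late_selfreport = quit_late_selfreport,
       covid_era = covid_era, saliva_provided = saliva_provided,
       site = site, adviser_grade = adviser_grade,
       sss_contact_minutes = sss_contact_minutes, nrt_weeks = nrt_weeks)
}

# Identity EQ-5D value set: every decrement zero.
identity_valueset <- function() {
  expand.grid(dimension = c("MO", "SC", "UA", "PD", "AD"),
              level = 1:5, stringsAsFactors = FALSE) |>
    transform(decrement = 0)
}

# Tiny deterministic table for GLM unit tests.
flat_two_arm_table <- function(n_per_arm = 20, value = 100) {
  tibble::tibble(
    arm = rep(c("incentives", "control"), each = n_per_arm),
    site = rep(1:2, n_per_arm),
    age_years = 30,
    y = value)
}

# Fast lifetime parameter set: shorter horizon keeps Markov loops cheap.
fast_lifetime_params <- function(...) {
  lifetime_params(max_age = 60, ...)
}
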