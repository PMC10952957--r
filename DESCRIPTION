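Package: quitinc
Title: Economic Evaluation of Financial Incentives for Smoking Cessation in
    Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-trial cost-effectiveness and cost-utility analysis of a
    contingent financial-incentive scheme for smoking cessation in pregnancy,
    together with a lifetime mother-infant decision-tree/Markov cohort model
    with probabilistic sensitivity analysis. Includes a synthetic trial-cohort
    generator with missing-at-random masking, a contingent voucher costing
    engine with neonatal preterm-proxy costs, Russell-standard quit outcomes
    and QALYs by area under the utility curve, covariate-adjusted incremental
    analyses with chained-equation multiple imputation, non-parametric
    bootstrap and cost-effectiveness acceptability curves, and a discounted
    cohort simulation over pregnancy, childhood and lifetime sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
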