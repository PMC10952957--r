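#!/usr/bin/env Rscript
# Lifetime mother-infant cost-utility model.
#
# Runs the pregnancy decision tree plus Markov sections for mother (to age
# 100) and infant (childhood to 15, then adulthood), deterministic and
# probabilistic, for the base case and the published sensitivity overlays
# (gaming, self-report, incentive size, relapse). Reports the break-even
# intervention cost at which the combined strategy stops being dominant.
# State costs, utilities and mortality are the package's documented
# synthetic defaults, so absolute magnitudes are illustrative; incremental
# structure, adjustments and dominance behaviour are the object of
# interest. Writes tables and the PSA cost-effectiveness plane under
# results/.

suppressPackageStartupMessages({
  library(quitinc)
  library(ggplot2)
})

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20230315L
n_psa <- if (length(args) >= 2) as.integer(args[[2]]) else 10000L

dir.create("results", showWarnings = FALSE)
params <- lifetime_params()

det <- run_lifetime(params)
cat("deterministic lifetime results (per mother, discounted 3.5%):\n")
print(as.data.frame(det[, c("scenario", "delta_cost", "delta_qaly",
                            "icer", "icer_label")]),
      digits = 4, row.names = FALSE)
alb <- attr(det, "adverse_live_births")
apo <- attr(det, "adverse_pregnancy_outcomes")
cat(sprintf("adverse live births (cohort): %.0f vs %.0f; adverse pregnancy outcomes: %.0f vs %.0f\n",
            alb[["incentives"]], alb[["control"]],
            apo[["incentives"]], apo[["control"]]))

be <- break_even_intervention_cost(params)
cat(sprintf("break-even intervention cost: £%.0f (current £%.0f); combined QALY gain %.3f\n",
            be$cost, params$intervention_cost[["incentives"]], be$delta_qaly))

if (n_psa > 0) {
  psa <- run_psa(params, n_samples = n_psa, seed = seed)
  cat(sprintf("\nPSA (%d samples): combined delta cost £%.0f (%.0f to %.0f), delta QALY %.3f (%.3f to %.3f)\n",
              n_psa,
              psa$summary$delta_cost[psa$summary$scenario == "combined"],
              psa$summary$delta_cost_lo[psa$summary$scenario == "combined"],
              psa$summary$delta_cost_hi[psa$summary$scenario == "combined"],
              psa$summary$delta_qaly[psa$summary$scenario == "combined"],
              psa$summary$delta_qaly_lo[psa$summary$scenario == "combined"],
              psa$summary$delta_qaly_hi[psa$summary$scenario == "combined"]))
  cat(sprintf("probability cost-effective at £%.0f/QALY: %.3f\n",
              params$wtp_reference, psa$prob_ce))
  utils::write.csv(psa$summary, "results/lifetime_psa_summary.csv",
                   row.names = FALSE)
  utils::write.csv(psa$samples, "results/lifetime_psa_samples.csv",
                   row.names = FALSE)
  ggsave("results/lifetime_ce_plane.png",
         ce_plane_plot(psa$samples, wtp = params$wtp_reference),
         width = 6, height = 5, dpi = 150)
}

cat("\nsensitivity overlays (combined mother + infant):\n")
scen <- run_all_scenarios(params, n_psa = min(n_psa, 2000L), seed = seed)
print(as.data.frame(scen[, intersect(c("scenario", "delta_cost",
                                       "delta_qaly", "icer", "icer_label",
                                       "prob_ce"), names(scen))]),
      digits = 4, row.names = FALSE)
utils::write.csv(det, "results/lifetime_deterministic.csv",
                 row.names = FALSE)
utils::write.csv(scen, "results/lifetime_scenarios.csv", row.names = FALSE)

run_manifest("lifetime", seed = seed,
             outputs = c("results/lifetime_deterministic.csv",
                         "results/lifetime_scenarios.csv"),
             path = "results/manifest_lifetime.json")
cat("wrote results/lifetime_*.csv\n")
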