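#!/usr/bin/env Rscript
# Within-trial cost-effectiveness and cost-utility analysis.
#
# Reads the simulated cohort, multiply imputes the disaggregated cost and
# utility inputs, and estimates covariate-adjusted incremental costs,
# late-pregnancy quit-rate and QALY differences, with ICERs, a stratified
# bootstrap, the cost-effectiveness plane and acceptability curve, and the
# ten sensitivity scenarios. Writes tables and figures under results/.

suppressPackageStartupMessages({
  library(quitinc)
  library(ggplot2)
})

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20230315L

if (!file.exists("results/cohort.csv")) {
  stop("results/cohort.csv not found; run analysis/01_simulate.R first")
}
table <- read_participants("results/cohort.csv")
config <- analysis_config(n_imputations = 10L, bootstrap_reps = 1000L,
                          seed = seed)

res <- run_within_trial(table, config)

cat("base case (pooled over", res$meta$m, "imputations):\n")
fmt <- function(x) sprintf("%.0f", x)
cat(sprintf("  incremental cost   £%s (95%% CI %s to %s) [%s model]\n",
            fmt(res$results$cost$estimate), fmt(res$results$cost$ci[1]),
            fmt(res$results$cost$ci[2]), res$results$cost$family_used))
cat(sprintf("  quit-rate difference %.3f (%.3f to %.3f); arm rates %.3f / %.3f\n",
            res$results$quit$estimate, res$results$quit$ci[1],
            res$results$quit$ci[2], res$results$quit_rate[["incentives"]],
            res$results$quit_rate[["control"]]))
cat(sprintf("  QALY difference     %.4f (%.4f to %.4f)\n",
            res$results$qaly$estimate, res$results$qaly$ci[1],
            res$results$qaly$ci[2]))
show_icer <- function(label, ic) {
  cat(sprintf("  ICER (%s): %s\n", label,
              if (ic$label == "ratio") {
                sprintf("£%.0f (reported £%.0f)", ic$value, ic$reported)
              } else ic$label))
}
show_icer("per quitter", res$icers$quitter)
show_icer("per QALY", res$icers$qaly)
ce20 <- res$ceac$probability[res$ceac$threshold == 20000]
cat(sprintf("  probability cost-effective at £20 000/QALY: %.2f\n", ce20))

utils::write.csv(res$arm_summary, "results/arm_cost_summary.csv",
                 row.names = FALSE)
utils::write.csv(res$samples, "results/bootstrap_samples.csv",
                 row.names = FALSE)
utils::write.csv(res$ceac, "results/ceac.csv", row.names = FALSE)
ggsave("results/ce_plane.png", ce_plane_plot(res$samples),
       width = 6, height = 5, dpi = 150)
ggsave("results/ceac.png", ceac_plot(res$ceac), width = 6, height = 4,
       dpi = 150)

cat("\nsensitivity scenarios:\n")
scen <- run_scenarios(table, config)
print(as.data.frame(scen[, c("scenario", "delta_cost", "delta_quit",
                             "delta_qaly", "icer_quitter_reported",
                             "icer_qaly_reported", "note")]),
      digits = 3, row.names = FALSE)
utils::write.csv(scen, "results/within_trial_scenarios.csv",
                 row.names = FALSE)

run_manifest("within-trial", seed = seed,
             outputs = c("results/arm_cost_summary.csv",
                         "results/bootstrap_samples.csv", "results/ceac.csv",
                         "results/ce_plane.png", "results/ceac.png",
                         "results/within_trial_scenarios.csv"),
             path = "results/manifest_within_trial.json")
cat("wrote results/within_trial_scenarios.csv and figures\n")
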