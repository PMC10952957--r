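---
title: "Methods: trial-based and lifetime economic evaluation of cessation incentives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based and lifetime economic evaluation of cessation incentives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitinc)
```

`quitinc` implements a two-part economic evaluation of contingent
financial incentives for smoking cessation in pregnancy: a within-trial
cost-effectiveness and cost-utility analysis, and a lifetime
mother–infant cohort model. Because the individual-level trial data are
not public, the package also implements a calibrated synthetic cohort
generator, and every downstream stage is specified, tested and exercised
against it. This vignette records the modelling assumptions, the
parameters that matter, the numerical choices, and what the synthetic
results do and do not show.

## The synthetic cohort generator

`cohort_spec()` declares the joint structure the generator reproduces;
`generate_cohort()` draws one complete table; `inject_missingness()`
masks it. The defaults are the study conditions:

* **Arms and sites.** 471 incentives / 470 control participants over
  seven sites. Site weights are uniform — site sizes were not reported —
  and are declared synthetic.
* **Milestone chain.** Engagement → 4-week quit → 12-week quit is
  generated as a chain with conditional continuation probabilities
  back-derived from the marginal targets (incentives arm 71.4%, 36.2%,
  29.2%), which guarantees the nesting invariant (12-week quitters ⊆
  4-week quitters ⊆ engagers) by construction. Late-pregnancy verified
  quit (0.268 / 0.123 by arm) is sticky from the 12-week state
  (continuation 0.75) with the recovery probability among the rest solved
  to hit the marginal. Post-partum sustained quit (0.079 / 0.051) is
  nested within late-pregnancy quitters.
* **Self-report and the voucher pathway.** A self-report layer sits above
  the verified status (marginals 0.359 / 0.185). In the incentives arm
  the covid-era conditional self-report rate is pinned so that the
  marginal late-voucher issuance matches the published 31.8% — covid-era
  self-reporters with a saliva sample earn the £200 voucher — and the
  pre-covid conditional absorbs the remainder. The covid-era fraction
  (0.30) was not reported and is a synthetic default.
* **Utilities.** Truncated normal on the declared value-set range
  [−0.594, 1], with the *location* parameter moment-matched by
  root-finding so the post-truncation mean equals the declared target
  (≈ 0.67–0.69 by arm and timepoint; SD 0.25, a typical EQ-5D dispersion,
  not reported in the source). This matches reported means without
  claiming the real distribution.
* **Preterm birth.** Quit-status-dependent class probabilities
  (smoker: 0.4% extremely, 1.0% very, 5.5% moderate-to-late preterm;
  quitter: roughly half), chosen so the implied arm mean neonatal costs
  fall between the two published arm means. They are synthetic defaults,
  not estimates: the published arm imbalance (higher neonatal costs in
  the *incentives* arm) was attributed to chance, and a generator with
  status-dependent risks cannot and should not reproduce it on average.
* **Missingness.** Marginal targets per variable follow the published
  missing-data table (e.g. 12% of NRT costs, 23% of late-pregnancy
  utilities, 28% of post-partum utilities). Masking probability is a
  logistic function of miscarriage and site only — missing at random by
  construction, verified by a property test regressing the missingness
  indicator on the masked values over 100 seeds. Support-cost missingness
  is nested inside NRT missingness, mirroring the published pattern where
  one is a subset of the other.
* **Seeding.** One master seed; every variable draws from a named
  substream (FNV-1a hash of the variable name), so adding a variable
  never perturbs existing draws, and identical spec + seed reproduces the
  table byte-for-byte.

A deliberate consequence of masking: the Russell-standard quit rate on a
masked cohort is *below* the generator marginal (missing counts as
smoker), so base-case quit-rate estimates sit slightly under
0.268 / 0.123. The published rates are already post-Russell; the
generator treats them as pre-masking marginals because the two cannot be
disentangled without the real missingness pattern.

## Costing

Unit costs are 2020 GBP. The voucher engine applies the contingency
rules exactly (each of £50/£50/£100 requires the previous milestone; the
£200 requires only the late-pregnancy quit, or covid-era self-report plus
saliva); a missing milestone is not achieved; an exclusion flag supports
issued-but-never-received vouchers. Postage attaches to every issued
voucher (£2.92), charged re-sends cost £2.05, uncharged re-sends £0.
Adviser contact is costed per hour by pay grade (£39/£49); the two
"typical use" sites substitute a configured site profile when individual
support data are absent. NRT is costed per prescribed week at a
configurable price (£16.50 default — the source formulary lists many
preparations and no single price). Neonatal stays are proxied by preterm
class: length of stay (13/44/93 days) × per-day cost
(£536.45/£709.16/£1707.50); term births cost zero; missing gestational
age propagates to imputation. Currency arithmetic is double precision
throughout; `round_pence()` (half-even) is reporting-only.

## Outcomes

Quit status follows the Russell standard: missing → smoker (recorded as
`imputed_smoker`); under the primary definition a reported quit needs
biochemical verification (CO, or covid-era self-report + saliva), and a
failed verification counts as smoker. The self-reported definition is a
sensitivity switch. QALYs are trapezoid areas under the utility
trajectory; follow-up interval lengths default to 0.5 years (baseline →
late pregnancy) and 0.65 years (→ 6 months post-partum), config-exposed,
consistent with in-trial QALYs of roughly a third of a year; the
post-partum QALY integrates the full follow-up. Fewer than two observed
utility points makes the QALY undefined (`NA`, flowing to imputation),
never silently zero.

## Within-trial estimation

* **Adjusted differences.** GLM with recycled predictions: the marginal
  arm effect is the mean predicted outcome with everyone assigned to the
  incentives arm minus the same under control. Costs default to gamma/log
  — standard for right-skewed costs — with an automatic, reported
  fallback to Gaussian/identity when the outcome contains non-positive
  values (zero-cost control participants are common here, so the Gaussian
  path is the one normally exercised) or the gamma fit fails. Quit rates
  and QALYs use Gaussian/identity. Intervals use a delta-method SE of the
  marginal effect. Covariate lists are fixed: site, age, years smoking
  and covid era for costs; site, age, baseline utility, booking
  gestational age and covid era for QALYs.
* **Multiple imputation.** `mice`-style chained equations implemented in
  the package: per-column regression imputation with coefficients
  perturbed by a draw from their sampling distribution and
  predictive-mean-matching donors (k = 5), 10 passes, m = 20 default
  (m = 10 in the analysis scripts; the number of imputations was not
  reported). Imputation acts on the disaggregated inputs (support
  minutes, NRT weeks, utilities); costs and QALYs are recomputed per
  completed table; estimates pool by Rubin's rules. Imputation is done
  once on the full table and the bootstrap resamples completed data,
  replicates spread evenly over the m tables — nesting imputation inside
  the bootstrap would multiply cost ~m-fold for little gain at these
  missingness levels.
* **ICER reporting.** Raw ratios are always retained; the reported value
  rounds to the nearest £100 below £10 000 and the nearest £1000 at or
  above, the rule that reproduces every published quitter-based cell.
  Dominance labels: dominant iff ΔC < 0 < ΔE; dominated iff ΔE < 0 < ΔC;
  undefined iff ΔE = 0. Two published cells cannot be reproduced from
  their own printed inputs (the base-case cost-per-QALY cell, whose
  rounded inputs give a different ratio, and the equalized-neonatal
  scenario's quitter ICER); `icer_consistency_flag()` detects exactly
  this situation and the scenario runner reports the computed ratio
  rather than matching either printed number.
* **Bootstrap and CEAC.** Participant-level resampling stratified by arm,
  1000 replicates, re-running the adjusted differences per replicate
  (point estimates only); failed replicate fits are redrawn and counted.
  CEAC(λ) is the fraction of replicates with λ·ΔE − ΔC > 0; at λ = 0 this
  is the probability of cost saving.
* **Scenarios.** S1 adds miscarriage as a covariate; S2 switches to
  self-reported quit; S3/S4 deflate quit rates proportionally (11%/20%,
  or 11% both arms) while keeping the base-case incremental cost, exactly
  as the published sensitivity treats gaming; S5/S6 switch to post-partum
  outcomes; S7 is complete case; S8 replaces every neonatal cost by the
  trial-wide mean; S9/S10 reprice postage at £6/£0.

## The lifetime model

Structure: a pregnancy decision tree (arm quit rate × status-specific
distribution over normal birth / adverse live birth / adverse pregnancy
outcome), then annual-cycle Markov cohorts — mother
(quitter/smoker/dead, age 28 to 100), infant childhood
(healthy/morbidity/dead, birth to 15) and infant adulthood
(smoker/non-smoker/dead, 15 to 100). The intervention cost is charged
once, in the tree, undiscounted; all later cycles discount at 3.5%.
First-cycle maternal relapse uses the 1-year post-partum relapse rate
(0.47; the trial-derived sensitivity substitutes 0.814 via
`extrapolate_relapse(method = "fixed")`, since the published
extrapolation is not derivable from the 6-month figure — constant-hazard
doubling is available as a method but gives a different value). Children
of post-partum smokers face a higher morbidity onset and a 1.9× relative
risk of smoking uptake at 15. Reporting scenarios are cumulative (infant
childhood includes the pregnancy-tree infant costs; adulthood includes
childhood), and the combined scenario is maternal lifetime + infant
lifetime, so the accounting identity `combined = maternal_lifetime +
infant_adulthood` holds exactly and is asserted in tests.

The external published lifetime model's state lists, morbidity/mortality
rates, state costs and utilities are not public. The defaults in
`lifetime_params()` are therefore **synthetic**, constructed to satisfy
the orderings the analysis depends on — quitter utility ≥ smoker utility,
quitter mortality ≤ smoker mortality (Gompertz baseline with hazard
ratios 1.15/1.8), smoking-attributable state costs ≥ 0 — and labelled as
such. Consequences: absolute lifetime magnitudes are illustrative and are
*not* compared against the published lifetime table; what the package
asserts instead are structural properties (mass conservation each cycle,
row-stochastic transitions, absorbing death, discount closed forms,
monotonicity of the combined QALY gain in the incentives quit rate, the
existence and correct reporting of a break-even intervention cost, and
dominance labelling exactly when ΔC < 0 < ΔQALY).

Numerical choices: cycle length 1 year; no half-cycle correction by
default (flag available; the published analysis is silent); occupancy
mass checked to 1e-8 relative each cycle; transition rows validated to
1e-9. PSA draws every uncertain parameter by method of moments — beta for
probabilities and utilities, gamma for costs — from mean/SE pairs; a zero
SE yields a degenerate distribution that returns the mean *without
consuming randomness*, so an all-degenerate PSA reproduces the
deterministic run bit-for-bit (asserted in tests). Pregnancy-outcome
probability draws renormalize into the normal-birth branch. The
break-even intervention cost is found by `uniroot` on the combined
incremental cost as a function of the incentives-arm intervention cost;
it exists whenever the lifetime health-care offsets are non-negative,
which the parameter orderings guarantee.

## Problem sizes

The test suite runs the full trial size (n = 941) for pipeline and
bootstrap checks (1000 replicates), n ≈ 9400 for calibration checks of
the voucher economics, 100 repetitions at n = 5000 for interval-coverage
of generator-truth recovery, and a shortened lifetime horizon (age 60)
where only structure is at stake. The analysis scripts use m = 10
imputations, 1000 bootstrap replicates and 10 000 PSA draws; the
acceptance script uses 2000 PSA draws. These sizes keep Monte-Carlo error
well inside the tolerances asserted while remaining quick to re-run.

## Limitations

* The generator reproduces marginal structure, not the real joint
  distribution: utilities are independent of quit status and site,
  resource use is light-tailed, and the published chance imbalance in
  neonatal costs is deliberately not reproduced. Passing tests
  demonstrate the *machinery* is correct, not that synthetic results
  match the real trial's point estimates.
* Lifetime magnitudes depend on synthetic state parameters; only
  directional and structural claims carry over.
* Patient-borne costs and spill-over effects are out of scope, as in the
  source analysis; no inflation machinery beyond a labelled price year.
* The EQ-5D crosswalk value set is consumed as data (two small CSV
  layouts under `inst/extdata/`, an identity test set and a clearly
  labelled synthetic decrement set); the published tariff is not
  reproduced.
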