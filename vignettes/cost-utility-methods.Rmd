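---
title: "Methods: a short-term cost-utility model of basal insulins driven by hypoglycaemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a short-term cost-utility model of basal insulins driven by hypoglycaemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulinCEA)
```

## The model

`insulinCEA` implements a deliberately simple decision model comparing
insulin degludec with biosimilar insulin glargine U100 in three diabetes
patient groups: type 1 on basal-bolus therapy (`T1DM_BB`), type 2 on basal
insulin plus oral agents (`T2DM_BOT`) and type 2 on basal-bolus therapy
(`T2DM_BB`). Because the underlying clinical evidence comes from
treat-to-target trials — both arms are titrated to the same glycaemic
target — there is no HbA1c difference to drive a long-term complications
model. What differs between the insulins is (i) the dose needed, (ii) the
rate of hypoglycaemic events, and (iii) a flexible-dosing convenience
benefit. The model therefore accounts, over a one-year horizon with no
discounting, for exactly two cost components and one utility ledger per
arm:

* **Costs**: annual insulin acquisition (`dose x unit price x 365`) plus
  hypoglycaemia management costs in three event categories — non-severe
  daytime, non-severe nocturnal, severe — each `rate x per-event cost`.
* **Effects (QALYs)**: a baseline annual utility, minus `rate x
  per-event disutility` in each category, minus an optional expected
  mortality loss after severe events, plus an annual flexible-dosing
  utility gain (base case 0.006) in the degludec arm.

Degludec doses and event rates are derived from the glargine values via
meta-analysis ratios, with *significance gating*: a ratio whose estimate
was not statistically significant is applied as 1 (`effective_ratio()`).
The headline result per group is the incremental cost-effectiveness ratio
(ICER), classified on the cost-effectiveness plane (`compare()`), with net
monetary benefit evaluated at the Bulgarian willingness-to-pay threshold
of 39,619 BGN/QALY (three times GDP per capita).

Because the model is annual and multiplicative, results for longer
horizons with zero discounting scale both the cost and QALY increments by
the same factor. The implementation computes the ICER from the *annual*
increments, so a 5-year run returns a bit-for-bit identical ICER rather
than one equal up to floating-point rounding. When a nonzero discount rate
is supplied (multi-year scenarios), annual compounding is applied
identically to costs and QALYs, which preserves the same invariance.

## Calibration: recovering unpublished unit parameters

The published analysis prints its aggregate results — per-arm annual
insulin and hypoglycaemia costs, QALYs and ICERs — but not the unit
parameters behind them: insulin unit prices, effective per-event costs,
per-event disutilities and baseline utilities. All of these enter the
model linearly, so they can be back-derived exactly from the printed
aggregates (`calibrate()`):

* **Basal unit prices** are identified by the basal-oral group, whose
  arms contain a single insulin each: `price = annual cost / (dose x 365)`.
  The days-per-year constant is not printed; 365 is used, and the
  back-derivation is consistent with that choice.
* **Bolus prices** come from the basal-bolus glargine arms' residual cost
  over their basal component, and each group's degludec basal price from
  the degludec arm's residual over its bolus component.
* **Per-event costs** are level solves, `glargine cost cell / glargine
  rate`, with the degludec arm (`cell / unrounded degludec rate`) as a
  within-group consistency check (all discrepancies are below 0.2%).
* **Disutilities** solve a triangular linear system across the three
  groups' QALY increments: the type 1 group has only a nocturnal rate
  difference, the basal-bolus type 2 group adds a daytime difference, and
  the basal-oral group adds a severe difference. Each increment is
  `flexible utility + sum(rate difference x disutility)`.
* **Baseline utilities** are the glargine-arm QALYs plus that arm's event
  disutility burden, cross-checked against the degludec arm.

Calibration is performed **per patient group** because the printed cells
are not jointly consistent with one global parameter set — for example the
implied severe per-event cost ranges from 499.0 to 507.8 BGN across
groups, and the implied bolus price differs by about 2.8% between the two
basal-bolus groups. These spreads are genuine features of the published
table (they presumably reflect rounding of intermediate quantities before
publication) and are reported in the `calibration_report` rather than
averaged away. With per-group parameters the forward model reproduces
every printed cost and QALY cell to well within 0.2% and the three ICERs
to within 1%; the largest ICER deviation (the basal-oral group, about
0.9%) traces to the printed nocturnal cost cells, whose implied per-event
costs differ slightly between arms.

Two modelling choices deserve emphasis:

* **Mortality after severe hypoglycaemia.** The analysis names a 1.12%
  mortality risk per severe event but not the QALY pathway attached to
  it. The disutility calibration would silently absorb any such pathway
  into the severe-event disutility, so the base case carries the risk
  parameter with `qaly_loss_per_death = 0` and exposes both fields for the
  zero-mortality scenario (which is then, intentionally, a no-op on the
  base case).
* **Daytime rate in the basal-oral group.** The published rate table
  prints 23.12 events/patient/year under glargine and 23.11 under
  degludec despite a non-significant ratio; this is treated as a rounding
  artefact and the glargine value is used for both arms.

Solved parameters are written to YAML configurations
(`write_calibration()`), and the forward model only ever consumes such
configurations — no derived number is hard-coded.

## One-way sensitivity analysis

`table4_scenarios()` encodes the published scenario set: a 5-year horizon,
zero mortality after severe events, per-event costs +/-10%, no dose
difference, no hypoglycaemia rate difference, an alternative
flexible-dosing utility (0.013), the benefit restricted to 50% of
patients, and no flexible-dosing benefit. Scenario application is pure
(the base parameters are copied, edited by dot-path, and revalidated), and
`run_scenarios()` tabulates increments, ICER and dominance per scenario.

The no-rate-difference scenario has a closed form — the insulin-cost
increment divided by the flexible-dosing utility — which the engine
reproduces exactly; with calibrated inputs this gives 36,783 BGN/QALY in
the basal-oral group and 62,990 BGN/QALY in the basal-bolus type 2 group
(the published figures are 36,739 and 63,239; the published no-difference
figure for type 1, 19,781, is about 2% off its own closed form
116.56/0.006 and is therefore only checked qualitatively). Alternative
published event-rate sets are referenced in the source but their values
are not printed; they can be supplied as additional `scenario_spec()`s
replacing the `glargine_rates.*` and `rate_ratios.*` paths.

`tornado()` generalises this to low/high sweeps ranked by the width of the
induced ICER interval. Sweeps that cross into dominance report a negative
cost/QALY ratio (flagged with the dominance class) so widths stay
comparable — the conventional tornado-plot treatment.

## Probabilistic sensitivity analysis

The source analysis reports acceptability probabilities but neither the
distribution families nor dispersions behind them, so exact reproduction
is not possible from the text and the package makes conventional choices,
all overridable per parameter (`dist_spec()`):

| parameter | family | CV | rationale |
|---|---|---|---|
| per-event costs | gamma | 0.20 | non-negative, right-skewed |
| dose and rate ratios | lognormal | 0.15 | positive, multiplicative |
| disutilities, flexible utility | beta | 0.20 | bounded utilities |
| unit prices, baseline utility, glargine rates | fixed | — | administered prices; baseline cancels in increments |

All families are moment-matched so the mean equals the deterministic
central value; a CV of 0 degenerates to the fixed base case, and the PSA
then reproduces the deterministic result to within 1e-6. **Non-significant
ratios are sampled around 1** (with the same CV) rather than pinned at 1.
This is an interpretive choice, made once and documented prominently: the
gating to 1 is a point assumption about an uncertain quantity, and holding
it fixed would make the acceptability curve overstate certainty —
particularly in the type 1 group, where the severe-event ratio is
non-significant but severe events dominate both costs and QALY losses.
Draw streams are seeded per parameter path, so adding a parameter to the
specification never perturbs the other parameters' draws, and results are
reproducible bit-for-bit given the seed. With n = 10,000 draws the
acceptability probabilities at the threshold computed by
`analysis/04_psa.R` (63.0%, 98.4% and 94.2% for `T1DM_BB`, `T2DM_BOT`,
`T2DM_BB` at seed 2024) fall in the same qualitative bands as the
published 60.0%, 99.4% and 91.3%, which is all that can be claimed given
the unpublished dispersions.

## Synthetic parameter sets

`random_parameters()` draws complete, valid parameter sets with event
rates within ten-fold of the published glargine rates, doses of 10-60
units/day and ratios in 0.5-1.3 — the neighbourhood a basal-insulin
comparison in practice could plausibly occupy. It emulates the *shape* of
the real inputs, not their correlation structure (parameters are drawn
independently) nor any patient-level event process, so passing tests
demonstrate arithmetical correctness of the pipeline rather than clinical
realism. `parameters_with_known_icer()` works backwards from the QALY side
to the prices — the only parameters entering costs linearly and
independently of the QALY ledger — so the constructed set's ICER is known
in closed form; the forward model recovers it to about 1e-14 relative,
which is the package's strongest end-to-end correctness check.

## Numerical choices

* Currency values are carried at full precision throughout; rounding to
  the published 2 decimals (4 for QALYs) happens only in the report
  writers.
* The ICER is formed from annual increments (horizon invariance is exact,
  see above) and only in the two ratio quadrants of the
  cost-effectiveness plane; dominance and indeterminate cases return `NA`
  rather than risking division by a zero QALY difference.
* Negative annual utilities (possible under extreme synthetic inputs) are
  floored at zero with a warning.
* Configuration parsing rejects unknown keys outright, so misspelled
  fields cannot silently fall back to defaults.
* Problem sizes: the packaged analyses use 10,000 PSA draws per group and
  100 synthetic recovery seeds, enough for about one-percentage-point
  Monte-Carlo noise on acceptability probabilities.

## Limitations

* The model covers no adverse events beyond hypoglycaemia and no
  HbA1c-driven complications — appropriate for treat-to-target evidence,
  but not a lifetime model.
* Calibrated disutilities and baseline utilities are *effective* values
  conditional on the published aggregates; whether they match the
  original elicitation sources cannot be established from the aggregates
  alone.
* PSA dispersions are assumptions; the acceptability probabilities should
  be read as qualitative bands.
* Self-monitoring of blood glucose costs are excluded (not reimbursed by
  the payer whose perspective the model takes), as in the source analysis.
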