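---
title: "Benchmark-dose methods for urinary cadmium and renal markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose methods for urinary cadmium and renal markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalbmd)
```

## The problem

Long-term cadmium exposure injures the kidney in a characteristic
sequence: proximal tubular reabsorption fails first (urinary
β2-microglobulin rises, the percent tubular reabsorption %TRβ2-MG falls),
then glomerular filtration declines (creatinine clearance, eGFR). To set
reference exposure levels, dose–response data are summarized as a
benchmark dose: the urinary cadmium concentration (µg/g creatinine) at
which the probability of an adverse response rises by a benchmark response
(BMR) of 5% or 10% over background, together with a one-sided lower 95%
confidence limit (BMDL).

`renalbmd` implements this workflow end to end for five endpoints —
CrCl, eGFR and ln U-β2-MG as continuous markers, and the dichotomized
flags %TRβ2-MG < 95% and < 90% — always stratified by sex and adjusted
for age, the only covariates available in cohorts of this design.

## Marker derivation

Raw analytes are converted to endpoints with the field's standard
formulas, at locked units (serum creatinine mg/dL by the Jaffe method,
urinary creatinine mg/mL, β2-MG µg/L, cadmium µg/L):

* Du Bois body surface area `0.007184·h^0.725·w^0.425` (h cm, w kg);
* 2-h creatinine clearance normalized to 1.73 m²;
* the Japanese Society of Nephrology eGFR equation
  `194·SCr^−1.094·age^−0.287 (×0.739 for women)`, fed Jaffe creatinine
  minus 0.2 mg/dL because the equation expects enzymatic values;
* creatinine correction of urinary concentrations to µg/g Cr;
* `%TRβ2-MG = (1 − U-β2MG·SCr·0.01/(S-β2MG·U-Cr))·100`.

Three policies here are the package's own choices, since none is dictated
by the source formulas: (1) %TR values below 0 — possible under severe
tubular failure — are reported as computed, never clamped, so that
dichotomization counts stay honest; (2) the 95/90 cut-offs use strict
`<`, so a subject exactly at 90.0 is not a case; (3) a Jaffe creatinine
at or below the 0.2 mg/dL offset invalidates eGFR for that record (the
record is flagged and carried, not dropped or floored — no floor is
defensible without an assay detection limit).

## Association models

Per sex, `y = β₀ + β₁·UCd + β₂·age + ε`. Continuous endpoints use OLS;
β2-MG is modeled on the natural-log scale, and exact zeros are excluded
with a count rather than shifted by a pseudo-count (no detection-limit
policy exists to justify one). Flags use binomial logistic regression
(IRLS, tolerance 1e-12, ≤ 100 iterations) with explicit errors for
single-class outcomes, complete separation, and non-convergence.

Interval choices are deliberately asymmetric: **t-based** CIs for OLS
(n ≈ 48–62 per sex makes the t/normal difference visible in the second
decimal) and **normal Wald** CIs for logistic fits — mirroring what SPSS
and most epidemiology software print, which is the likeliest provenance
of coefficient tables in this literature.

An endpoint proceeds to BMD estimation only if the dose term is
significant (two-sided p < 0.05). Skipped endpoints still appear in the
output table, as explicit `skipped (p >= 0.05)` rows.

## BMD and BMDL

**Hybrid approach** (continuous): with background adverse probability
P(0) fixed at 0.05, the cut-off sits at the `P(0)` tail quantile of the
endpoint distribution at dose 0 and reference age 70; under additional
risk the BMD is `(z₁₋P(0) − z₁₋P(0)−BMR)·σ/|β₁|`. The package verifies
this closed form against a numeric tail-probability root-find (1e-8) in
the test suite. For ln-β2-MG the cut-off is exponentiated for reporting;
adversity direction is per endpoint (low for CrCl/eGFR, high for β2-MG),
and a dose slope signed away from adversity is refused, not silently
absolute-valued.

**Additional vs extra risk.** The default is additional risk
(`P(d) − P(0) = BMR`): only the additional-risk formula reproduces the
published logistic benchmark doses from their own printed inputs (e.g.
OR 1.17 with background 11.8% gives 2.62 → 2.6, where extra risk gives
2.3). Extra risk (`(P(d) − P(0))/(1 − P(0)) = BMR`) is kept as an option;
the two differ even in their BMR-10%/BMR-5% ratios (1.6747 vs 1.6815),
which the tests pin separately.

**Logistic endpoints**: P(0) is estimated from the fit at the reference
age (70, configurable — whether a mean age would be more faithful is
unknowable from printed tables alone), and
`BMD = [logit(P(0)+BMR) − logit(P(0))]/β₁`, independent of the age slope
once P(0) is fixed.

**BMDL methods.** Three are provided because the method behind published
BMDLs of this kind is typically unstated:

* `profile` (default): smallest d₀ whose constrained fit (BMD pinned at
  d₀ by tying the dose slope to σ, or to the background-reparameterized
  intercept in the logistic case) keeps the likelihood-ratio statistic
  within 2.706 (`qchisq(0.90, 1)`); bracket failure falls back to the
  delta method with a warning.
* `delta`: `BMD·exp(−1.6449·SE(ln BMD))`, with
  `Var(ln BMD) = Var(β₁)/β₁² + 1/(2(n−3))` for the hybrid case (the
  second term is the ln-scale variance of σ̂) and a numeric gradient
  through (intercept, dose, age) for the logistic case.
* `slope_bound`: the closed form at the one-sided 95% bound of the dose
  slope. Kept for sensitivity analysis: applied to printed coefficients
  it demonstrably *under*-shoots published BMDLs (OR upper bound 1.35
  gives 1.37 vs a published 1.8), which is why it is not the default.

Normal quantiles come from `qnorm` (no table lookups); doses are held at
full precision internally and rounded half-up to one decimal only in the
report layer (`4.649 → "4.6"`, `2.65 → "2.7"`).

## The synthetic cohort

The original cohort (1980s Kakehashi River Basin survey; 30 exposed men,
44 exposed women, 18 + 18 controls, all over 50) is not deposited, so the
generator emulates its published structure:

* stratum sizes, age means/SDs (74.1/7.8, 73.2/7.2, 62.9/9.9, 63.9/9.0 y)
  and lognormal U-Cd GM/GSD (9.0/1.6, 11.6/1.7, 1.9/1.7, 4.8/1.5 µg/g Cr);
* ages truncated at 50 by rejection sampling. Note the truncation raises
  the realized mean of the youngest stratum by ≈ 1.2 y over its nominal
  63.9; tests therefore check the truncated-normal mean, not the nominal
  parameter;
* dose–response truth equal to the published age-adjusted coefficients
  per endpoint and sex; residual SDs backed out of the published BMR-5%
  benchmark doses via the closed form (women CrCl 19.45, men eGFR 16.00,
  ln-β2-MG 2.31/1.78). The two endpoints that failed the published
  significance gate have no recoverable σ and borrow the other sex's —
  they exist in the generator only so the gate has something to skip;
* linear intercepts moment-matched at sex-pooled mean age and mean U-Cd;
  logistic intercepts set so P(0) at age 70 equals the published
  backgrounds. `scripts/calibrate_defaults.R` regenerates all frozen
  constants;
* residuals independent across endpoints (the joint correlation structure
  is unpublished — this is the one structural assumption a green test
  cannot defend);
* **analyte mode** (default) back-solves serum/urine chemistry — serum
  creatinine by inverting the eGFR equation, 2-h urine volume by
  inverting the clearance formula, urinary concentrations from lognormal
  urinary creatinine (GM 1.0 mg/mL, GSD 1.6), serum β2-MG lognormal
  around 2000 µg/L (GSD 1.3), heights/weights plausible for an elderly
  1980s Japanese cohort — so that `derive_panel()` reproduces the drawn
  endpoints to machine precision and the %TR flags emerge mechanically
  from the chemistry. Rows whose drawn CrCl or eGFR is non-positive are
  redrawn (bounded at 100 retries). **endpoint mode** draws the flags
  directly from the logistic truth instead, for clean logistic-recovery
  tests. Both pipelines are exercised.

A green test suite therefore establishes: formula correctness, estimator
correctness (normal-equations and score-equation oracles), closed-form/
numeric BMD agreement, ≈ 95% one-sided BMDL coverage and BMD recovery
within 10% at study-like scale — under the *stated* world. It does not
establish anything about intra-individual variation, BMI, exercise,
diurnal collection effects, or endpoint correlation, none of which the
generator models.

## Known limitations

* Published BMDLs cannot be reproduced from printed coefficients alone
  (the confidence-limit method is unstated); only BMDs are anchored.
* Coefficient tables themselves are only recoverable in distribution, not
  value: the raw data are unavailable.
* No pooled-sex model, no covariates beyond age, no alternative eGFR
  equations, and no non-normal continuous BMD models — all deliberately
  out of scope.
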