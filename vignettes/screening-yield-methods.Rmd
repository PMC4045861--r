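---
title: "Methods: modelling the yield of diabetes screening guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the yield of diabetes screening guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The estimation problem

Screening guidelines for type 2 diabetes disagree about whom to test. The
ADA criteria target everyone aged 45 and older plus overweight or obese
adults of any age with at least one additional risk factor; the 2008-era
USPSTF criteria target only adults with sustained hypertension. Which rule
finds more of the undiagnosed disease, and at what screening cost?

No single survey can answer this. Lab-examined surveys (NHANES-like)
measure glycemia but not health-care use; expenditure surveys (MEPS-like)
record visits and conditions but draw no blood. The analysis therefore
proceeds in two stages:

1. **Model stage.** On the lab survey, classify every non-pregnant adult
   without diagnosed diabetes into normal / prediabetes / undiagnosed
   diabetes from their lab panel, and fit a survey-weighted polytomous
   logistic model of that outcome on demographics, conditions, body-weight
   class, income, insurance and survey wave. A companion binary logistic
   model predicts *diagnosed* prediabetes.
2. **Projection stage.** Evaluate both models on every adult of the second
   survey. The difference p(total prediabetes) − p(diagnosed prediabetes),
   clamped at zero, is the probability of *undetected* prediabetes. A
   screening rule assigns each record an annual screening fraction; expected
   screened and detected totals are fraction- and weight-weighted sums.

The detected totals are expectations, never integerised: a respondent with
weight 1,000, screening fraction 1, p(undetected prediabetes) = 0.3 and
p(undiagnosed diabetes) = 0.1 contributes exactly 1,000 screened persons,
300 expected prediabetes detections and 100 expected diabetes detections.
This identity is the package's most basic acceptance check.

## Classification rules

Diabetes: HbA1c ≥ 6.5%, FPG ≥ 126 mg/dL, or 2-h OGTT ≥ 200 mg/dL on *any*
available test. Prediabetes (when no test is in the diabetes range): HbA1c
5.7–6.4%, FPG 100–125, or OGTT 140–199. The printed inequalities leave
non-integer values such as FPG 125.5 unassigned; `classify_lab()` interprets
the intervals as half-open, anchored at the diabetes cut-points
(prediabetes FPG is `[100, 126)`), so such values fall in the lower
category. A diagnosed-diabetes flag dominates the lab category; lab
prediabetes is split by the diagnosed-prediabetes flag.

Exclusions remove pregnant women and diagnosed diabetes before modelling.
A record that is both is counted once, attributed to pregnancy — the
attribution order is fixed only so that logs are reproducible.

## The fitter

`fit_polytomous()` maximises the weight-multiplied multinomial
log-likelihood by full Newton–Raphson (analytic score and observed
information, reference category = normal). Numerical contract:

* convergence when the largest absolute score element is below `tol`
  (default 1e-8) with weights normalised to mean 1 — the normalisation
  makes estimates *and* the stopping rule exactly invariant to rescaling
  all weights by a positive constant;
* at most 100 Newton steps, with step-halving whenever a full step would
  decrease the log-likelihood;
* a ridge of 1e-6 on the Hessian diagonal only if it is singular;
* non-convergence raises an error carrying the last iterate; an empty
  outcome category raises a degenerate-data error up front.

Weights enter as frequency-style multipliers (pseudo-MLE). Reported
standard errors are model-based — the inverse observed information at the
optimum, computed on mean-1 weights so they live on the sampling scale of
*n* records. They ignore the design effect of unequal weighting (with the
default log-normal weights, independent of covariates, they are modestly
anti-conservative); design-based variance estimation is deliberately out of
scope. The same machinery with K = 2 is `fit_binary()`.

Goodness of fit uses pairwise concordance over positive–negative outcome
pairs: `concordance()` computes percent concordant / discordant / tied,
Somers' D = (C − D)/P and c = (C + T/2)/P with an O(n log n) rank-based
algorithm (Mann–Whitney statistic plus a tie table); ties are *exact*
floating-point equality, no rounding. The test suite checks it against an
explicit O(n²) pair-enumeration oracle on hundreds of random instances.

## Screening rules

Rules are declarative objects over the covariate table. USPSTF eligibility
uses the diagnosed-hypertension indicator as the proxy for "sustained blood
pressure > 135/80 mm Hg" — the projection survey has no measured blood
pressure; this is a documented proxy decision. ADA eligibility is
`age 45+ OR (overweight/obese AND ≥ 1 risk factor)`, with "age 45+" mapped
to the 45–54 band and above because age is banded. The default risk-factor
set is what the projection survey can observe: hypertension, high
cholesterol, cardiovascular disease, and high-risk (non-white)
race/ethnicity. Family history, inactivity, PCOS, gestational diabetes and
acanthosis nigricans are unobservable here and omitted; the set is an
argument of `ada_rule()` and can be replaced.

Obesity alone does not satisfy the weight clause: the criteria require an
*additional* risk factor beyond excess weight, so an obese record with no
other factor (and under 45) is ineligible. That reading is the stricter of
the two possible ones and is easy to change via the risk-factor list for
sensitivity analyses.

A person eligible *only* through age is screened with annual fraction 1/3,
modelling the three-year re-screening cycle; anyone on the
weight-plus-risk-factor path gets fraction 1. Fractions are applied as
deterministic expected-value multipliers — the wording "probability of
being screened during the year" supports the expectation interpretation,
and it keeps all totals exactly linear. The same fraction multiplies both
the screened total and the detected totals, also inside subgroup tables.

## Calibration

Cross-survey projections inherit any level mismatch between the two
surveys. `calibrate_scale()` computes the single factor
s = Σ targets / Σ predictions that aligns the summed national predictions
with external (CDC-style) case totals; s rescales every profile's
undiagnosed-diabetes and undetected-prediabetes probabilities (the
projection functions take it as `scale`). With predictions of 88.2 million
combined cases against a target of 86.0 million the factor is ≈ 0.975,
which is also the value the motivating US-2010 analysis applied.

## The synthetic-data generator

The generator exists so every downstream stage is testable without
restricted microdata; it is first-class, tested code.

**What it emulates.** Covariates are drawn from marginals loosely matched
to a US adult lab-survey population (48% male; six age bands; 70/11/5/14%
race/ethnicity mix; BMI-class mixture tilting toward excess weight with
age; chronic-condition prevalences rising on the logit scale with age band
and BMI class; 21% smokers; log-normal income with median $40k; 78%
insured; four equal survey waves; 2% pregnancy among women). The latent
glycemic state is drawn from the configured polytomous model — by default
the logs of published national-survey odds ratios as slopes for *both*
equations (the published table pools them), with intercepts calibrated once
by simulation (n = 400,000) so the latent mix is 54% normal / 30.3%
prediabetes / 15.7% diabetes, matching the source survey's category counts.
Diagnosis flags: P(diagnosed | prediabetes) is covariate-dependent
(published diagnosed-prediabetes odds ratios) with its intercept calibrated
so ~10% of prediabetes is diagnosed — i.e. ~90% undetected;
P(diagnosed | diabetes) is a constant 0.685. Keeping the latter
covariate-independent is deliberate: it shifts only the intercept of the
undiagnosed-diabetes equation, leaving its slopes equal to the latent-state
slopes, so the generating values are the *exact* recovery target for the
fitter (the recovery suite fits 20 replicate surveys of n = 50,000 and
requires ≥ 95% of slopes within 3 SE).

Lab panels: HbA1c always assigned, FPG with probability 0.48, OGTT 0.31,
independently; a record assigned nothing gets HbA1c so that everyone is
classifiable. Values are drawn uniformly over each category's defining
interval (prediabetes on the printed closed intervals, e.g. HbA1c
[5.7, 6.4]; diabetes capped at HbA1c 14, FPG 300, OGTT 400) — the analysis
only ever uses range membership, so the within-range shape is immaterial,
and uniform is the least-assumptive choice. All assigned tests agree with
the latent category unless `discordance_rate > 0`, a switch provided for
robustness testing only, because any-test classification makes discordance
parameters unidentifiable from the published material.

Visit counts (projection survey) are negative binomial (size 1,
configurable; `Inf` gives Poisson) with per-setting means linear in the
record's true undiagnosed-diabetes probability,
`mean = base + slope · p`. Defaults put low-risk adults (p < 0.05) near
4–5 total annual visits and high-risk adults (p ≥ 0.10) near 10–11,
concentrated in office-based care — reproducing the qualitative gradient
(more visits at higher undetected risk) seen in US expenditure data. An
optional zero-inflation probability models never-attenders. Sampling
weights are log-normal (median 9,000, sdlog 0.7), independent of
covariates, since the source material gives no weight model.

**What it does not emulate**, hence what passing tests do not show about
real data: complex survey design (strata/PSUs — only weights are
modelled); covariate correlations beyond the age/BMI conditioning;
within-category lab-value distributions; test discordance (by default);
measurement error and confirmatory retesting; secular trends beyond the
wave indicators. Because both generating equations share one pooled slope
vector, the synthetic spread of undiagnosed-diabetes probabilities
(~0.002–0.10) is narrower than the spread a model with outcome-specific
slopes produces on real data; conclusions about tail behaviour should not
be read off the synthetic scenario.

**Reproducibility.** Each generator call draws from a single RNG stream
seeded from the configuration and restores the caller's RNG state; a given
(config, seed) is bit-reproducible. (Per-record derived sub-streams were
considered and rejected: they add nothing observable here and are slow in
vectorised R.)

## Utilization and validation analyses

`utilization_by_band()` stratifies weighted mean annual visits per setting
by predicted-risk band; bands are half-open `[lo, hi)` with the last band
closed at 1, matching the "0.05 to <0.10" phrasing of published tables.
`primary_care_opportunity()` counts, within a rule's fraction-weighted
screened population, the persons with ≥ 1 primary-care *office* visit
(outpatient departments do not count) and the share of detectable cases
reachable there.

`split_sample_validate()` permutes the classified model survey with a
seeded RNG, fits on the first half (the extra record goes to the first
half when n is odd — 19,056 records give exactly 9,528 + 9,528), predicts
the held-out half, and tabulates predicted against observed weighted case
totals by age band, plus the maximum and mean absolute slope difference
between the two half-fits (the published criterion "similar coefficients"
is informal, so both summaries are reported). The split is simple random,
not stratified, matching "randomly divided"; under correct specification
the predicted/observed ratios converge to 1, which the test suite checks
at n = 40,000 for bands with substantial expected counts.

## Problem sizes used by the test suite

Chosen to make sampling error negligible relative to the tested
tolerances: marginal goodness-of-fit at n = 50,000; latent-share and
diagnosis-rate checks at n = 30,000; slope-recovery acceptance at 20
replicates of n = 50,000; bias-decrease property at n ∈ {5,000, 20,000,
80,000}; split-sample calibration at n = 40,000; oracle-equivalence suites
at 500 concordance instances (n ≤ 300) and the full 288-combination
eligibility grid.

## Known limitations

* Model-based SEs understate design-based uncertainty under informative
  weighting; fine for recovery testing (weights here are independent noise),
  not a substitute for survey variance estimation on real data.
* The undetected-prediabetes clamp max(0, ·) introduces a small upward bias
  where the diagnosed-prediabetes model overshoots the total-prediabetes
  probability; the published material does not address the negative case.
* Single-year expectation only: the 1/3 fraction approximates the
  three-year ADA cycle in steady state; no multi-year dynamics.
* Whether the diagnosed-prediabetes probability should be predicted for all
  adults or only those predicted prediabetic is ambiguous in the source
  description; the subtraction formula implies all, which is what
  `predict_risk()` does.
* No cost or cost-effectiveness estimation, and no false-positive modelling
  (no confirmatory retest exists in the lab survey).
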