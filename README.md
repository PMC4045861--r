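# screenyield

Model-based estimation of the *yield* of diabetes screening guidelines: how
many asymptomatic US adults would be screened, and how many cases of
undiagnosed type 2 diabetes and undetected prediabetes would be found, under
the American Diabetes Association (ADA) criteria versus the 2008-era US
Preventive Services Task Force (USPSTF) criteria.

The package is aimed at health-services and epidemiology researchers who
want to reproduce or extend this style of cross-survey screening-policy
analysis, and at methodologists who need its building blocks (survey-weighted
multinomial fitting, concordance diagnostics, declarative eligibility rules)
with a fully testable synthetic-data path.

## The method

Two surveys play different roles. A *model survey* (NHANES-like) carries a
glycemic lab panel — HbA1c (%), fasting plasma glucose (mg/dL), and/or 2-h
OGTT (mg/dL) — plus self-reported diagnoses. After excluding pregnant women
and diagnosed diabetes, each adult is classified from the labs
(diabetes if any test is in the diabetes range: HbA1c ≥ 6.5, FPG ≥ 126,
OGTT ≥ 200; prediabetes if any test is in 5.7–6.4 / 100–125 / 140–199) and a
survey-weighted polytomous logistic model is fitted for the three-category
outcome Y ∈ {normal, prediabetes, undiagnosed diabetes}:

```
log P(Y = k | x) / P(Y = normal | x) = x' β_k ,  k ∈ {prediabetes, undiag. diabetes}
```

with a companion binary logistic model for *diagnosed* prediabetes. The
fitted model is projected onto a *projection survey* (MEPS-like) that has no
labs but records annual health-care visits. For each adult there, the model
yields p(undiagnosed diabetes) and p(undetected prediabetes) =
p(total prediabetes) − p(diagnosed prediabetes), clamped at 0. A screening
rule maps each record to an annual screening fraction f (ADA: 1 for
overweight/obese with a risk factor, 1/3 for age-45+-only eligibility from
the three-year re-screening cycle; USPSTF: 1 for hypertension). Expected
totals are weighted sums — a record with sampling weight w contributes
`w·f` screened persons and `w·f·s·p` expected detected cases, where `s` is a
national-calibration factor. Utilization analyses stratify visit counts by
predicted-risk band; split-sample validation refits the model on a random
half-sample and checks predicted against observed case totals by age band.

Because the original survey microdata are not redistributable, the package
ships a first-class synthetic-data module (`generate_model_survey()`,
`generate_projection_survey()`) whose generating model — log odds-ratio
slopes from published national-survey regressions, calibrated intercepts,
partial lab-panel assignment (100% HbA1c / 48% FPG / 31% OGTT), ~90% of
prediabetes undetected, visit counts rising with latent risk — defines the
conditions under which every stage is tested.

## Worked example

```r
library(screenyield)

cfg <- scenario_config(population_size = 20000, seed = 42)
model_survey <- generate_model_survey(cfg)
nhanes_like <- apply_exclusions(model_survey)$kept   # drops pregnant + diagnosed DM
nhanes_like$status <- assign_status(nhanes_like)

fit   <- fit_polytomous(nhanes_like)                 # 3-category risk model
dfit  <- fit_binary(nhanes_like, "diagnosed_prediabetes")
model <- risk_model(fit, dfit)

proj <- apply_exclusions(generate_projection_survey(
  scenario_config(population_size = 20000, seed = 43)))$kept
profiles <- predict_risk(proj, model)

cmp <- compare_rules(proj, profiles, ada_rule(), uspstf_rule(), scale = 0.975)
print(cmp$result_a)
```

```
Screening projection
  screened:            104,016,519 persons
  detected diabetes:   7,896,464
  detected prediabetes:40,039,935
  screened per diabetes case: 13.2
  screened per any case:      2.2
```

The screened total is the fraction-weighted population meeting the ADA
criteria; the detected counts are expected cases (sums of weight × fraction
× calibrated probability), and the final two lines are the
screening-efficiency ratios. Comparing the rules on the same population:

```r
cat(sprintf("ADA detects %.1f%% more diabetes and %.1f%% more prediabetes than USPSTF\n",
            cmp$pct_more_dm, cmp$pct_more_predm))
#> ADA detects 59.7% more diabetes and 71.0% more prediabetes than USPSTF

concordance(predict_risk(nhanes_like, model)$p_undiag_dm,
            as.integer(nhanes_like$status == "undiagnosed_diabetes"))
#> Concordance over 16,381,404 positive-negative pairs
#>   concordant 68.8%  discordant 31.2%  tied 0.0%
#>   Somers' D 0.377   c-statistic 0.688

primary_care_opportunity(proj, profiles, ada_rule(), scale = 0.975)
#> Primary-care screening opportunity
#>   screened population:          104,016,519
#>   with >=1 primary-care visit:  61,544,708 (59.2%)
#>   detectable diabetes reachable:    61%
#>   detectable prediabetes reachable: 60%
```

(The exact gain percentages depend on the synthetic scenario; the published
US-2010 analysis that motivates the default scenario found smaller relative
gains on the real surveys.)

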