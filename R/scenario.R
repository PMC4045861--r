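# Scenario configuration for the synthetic surveys.

#' Default covariate distribution parameters
#'
#' Marginal and conditional distribution parameters for the synthetic
#' population: sex share, age-band and race/ethnicity mixtures, BMI-class
#' probabilities that shift toward excess weight with age, chronic-condition
#' prevalences that rise on the logit scale with age band and BMI class,
#' smoking and insurance rates, a log-normal family-income distribution
#' (thousands of 2010 dollars), survey-wave mixture, and the pregnancy rate
#' among women. Values are loosely matched to the descriptive statistics of a
#' US adult lab-examined survey population; they are scenario defaults, not a
#' calibrated reconstruction.
#'
#' @return Named list of covariate parameters.
#' @export
default_covariate_spec <- function() {
  list(
    p_male = 0.48,
    age_probs = setNames(c(0.30, 0.17, 0.16, 0.14, 0.11, 0.12), .age_levels),
    race_probs = setNames(c(0.70, 0.11, 0.05, 0.14), .race_levels),
    bmi_base_probs = setNames(c(0.37, 0.33, 0.30), .bmi_levels),
    bmi_age_shift = 0.12,
    condition_base = c(asthma = 0.12, arthritis = 0.05, heart_attack = 0.005,
                       stroke = 0.005, cancer = 0.02, hypertension = 0.08,
                       high_cholesterol = 0.08, cvd = 0.01),
    condition_age_slope = c(asthma = 0, arthritis = 0.55, heart_attack = 0.50,
                            stroke = 0.50, cancer = 0.50, hypertension = 0.50,
                            high_cholesterol = 0.50, cvd = 0.55),
    condition_bmi_slope = c(asthma = 0.10, arthritis = 0.20, heart_attack = 0.10,
                            stroke = 0.10, cancer = 0, hypertension = 0.50,
                            high_cholesterol = 0.50, cvd = 0.20),
    smoking_rate = 0.21,
    income_meanlog = log(40),
    income_sdlog = 0.75,
    insured_rate = 0.78,
    medicaid_rate = 0.06,
    wave_probs = setNames(rep(0.25, 4), .wave_levels),
    pregnancy_rate = 0.02
  )
}

#' Default visit-count distribution parameters
#'
#' Per-setting annual visit counts are drawn from negative binomial
#' distributions whose means rise linearly in the person's true probability of
#' undiagnosed diabetes: `mean = base + risk_slope * p`. Defaults are chosen
#' so that low-risk adults (p < 0.05) average about 4-5 total visits a year
#' and high-risk adults (p >= 0.10) about 10-11, concentrated in office-based
#' care, mirroring the utilisation gradient observed in US expenditure-survey
#' data. `zero_inflation` is the probability of a structural zero applied to
#' every setting; `dispersion` is the negative binomial size parameter
#' (`Inf` gives Poisson counts).
#'
#' @return Named list of visit parameters.
#' @export
default_visit_spec <- function() {
  list(
    base = c(primary_care_office = 0.85, non_primary_office = 2.60,
             outpatient = 0.22, emergency = 0.11, inpatient_admissions = 0.04),
    risk_slope = c(primary_care_office = 11, non_primary_office = 32,
                   outpatient = 8, emergency = 1.2, inpatient_admissions = 1.4),
    zero_inflation = 0,
    dispersion = 1.0
  )
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    config_error(field, "must be probabilities in [0, 1]")
  }
  invisible(x)
}

check_mixture <- function(x, field, levels) {
  check_prob(x, field)
  if (!identical(names(x), levels)) {
    config_error(field, paste0("must be named ", paste(levels, collapse = ", ")))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    config_error(field, "must sum to 1 (within 1e-9)")
  }
  invisible(x)
}

#' Declare a synthetic-survey scenario
#'
#' A scenario bundles everything the generators need: the population size,
#' the RNG seed, the covariate distributions, the generating ("true") risk
#' model, the lab-panel assignment probabilities, the visit-count model for
#' the projection survey, and the sampling-weight distribution. All
#' parameters are validated eagerly; an invalid value raises a configuration
#' error naming the offending field.
#'
#' @param population_size Number of person records to generate (>= 1).
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   seed and configuration.
#' @param covariate_spec See [default_covariate_spec()].
#' @param true_model A [true_coefficients()] object.
#' @param lab_assignment Named probabilities that a model-survey record
#'   carries each glycemic test. Defaults (HbA1c 1.00, FPG 0.48, OGTT 0.31)
#'   match the test mix of the lab-examined survey the analysis emulates. A
#'   record assigned no test at all is given an HbA1c value so that every
#'   model-survey record is classifiable.
#' @param discordance_rate Probability that an assigned test is drawn from a
#'   different glycemic category than the latent state (default 0: all tests
#'   agree with the latent category).
#' @param visit_spec See [default_visit_spec()].
#' @param weight_spec Log-normal sampling-weight parameters
#'   (`meanlog`, `sdlog`); weights are strictly positive.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(population_size = 20000,
                            seed = 1,
                            covariate_spec = default_covariate_spec(),
                            true_model = default_true_coefficients(),
                            lab_assignment = c(hba1c = 1.00, fpg = 0.48,
                                               ogtt = 0.31),
                            discordance_rate = 0,
                            visit_spec = default_visit_spec(),
                            weight_spec = list(meanlog = log(9000),
                                               sdlog = 0.7)) {
  if (!is.numeric(population_size) || length(population_size) != 1 ||
      is.na(population_size) || population_size < 1 ||
      population_size != round(population_size)) {
    config_error("population_size", "must be a positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }
  if (!inherits(true_model, "true_coefficients")) {
    config_error("true_model", "must be a true_coefficients object")
  }

  cs <- covariate_spec
  check_prob(cs$p_male, "covariate_spec$p_male")
  check_mixture(cs$age_probs, "covariate_spec$age_probs", .age_levels)
  check_mixture(cs$race_probs, "covariate_spec$race_probs", .race_levels)
  check_mixture(cs$bmi_base_probs, "covariate_spec$bmi_base_probs", .bmi_levels)
  check_mixture(cs$wave_probs, "covariate_spec$wave_probs", .wave_levels)
  for (f in c("smoking_rate", "insured_rate", "medicaid_rate",
              "pregnancy_rate")) {
    check_prob(cs[[f]], paste0("covariate_spec$", f))
  }
  check_prob(cs$condition_base, "covariate_spec$condition_base")
  if (!identical(names(cs$condition_base), .condition_vars)) {
    config_error("covariate_spec$condition_base",
                 "must be named by the eight condition variables")
  }
  if (!is.numeric(cs$income_sdlog) || cs$income_sdlog < 0) {
    config_error("covariate_spec$income_sdlog", "must be non-negative")
  }

  if (!identical(names(lab_assignment), c("hba1c", "fpg", "ogtt"))) {
    config_error("lab_assignment", "must be named hba1c, fpg, ogtt")
  }
  check_prob(lab_assignment, "lab_assignment")
  check_prob(discordance_rate, "discordance_rate")

  vs <- visit_spec
  if (!identical(names(vs$base), .visit_vars) ||
      !identical(names(vs$risk_slope), .visit_vars)) {
    config_error("visit_spec", "base and risk_slope must be named by the five settings")
  }
  if (any(vs$base < 0) || any(vs$risk_slope < 0)) {
    config_error("visit_spec", "base means and risk slopes must be non-negative")
  }
  check_prob(vs$zero_inflation, "visit_spec$zero_inflation")
  if (!is.numeric(vs$dispersion) || vs$dispersion <= 0) {
    config_error("visit_spec$dispersion", "must be positive (Inf for Poisson)")
  }

  if (!is.numeric(weight_spec$meanlog) || !is.numeric(weight_spec$sdlog) ||
      weight_spec$sdlog < 0) {
    config_error("weight_spec", "must provide meanlog and non-negative sdlog")
  }

  structure(
    list(population_size = as.integer(population_size),
         seed = as.integer(seed),
         covariate_spec = cs,
         true_model = true_model,
         lab_assignment = lab_assignment,
         discordance_rate = discordance_rate,
         visit_spec = vs,
         weight_spec = weight_spec),
    class = "scenario_config"
  )
}
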