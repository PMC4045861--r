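# Design-vector layout shared by the generator, the model fitters and the
# rule engine. All categorical covariates are banded; each band enters the
# design as a treatment-coded indicator block with the first level as
# reference. Family income is the single continuous covariate (thousands of
# 2010 dollars).

.age_levels  <- c("18-34", "35-44", "45-54", "55-64", "65-74", "75+")
.race_levels <- c("nh_white", "nh_black", "nh_other", "hispanic")
.bmi_levels  <- c("normal", "overweight", "obese")
.wave_levels <- c("2003-04", "2005-06", "2007-08", "2009-10")

.condition_vars <- c("asthma", "arthritis", "heart_attack", "stroke", "cancer",
                     "hypertension", "high_cholesterol", "cvd")
.flag_vars <- c(.condition_vars, "smoker")

.visit_vars <- c("primary_care_office", "non_primary_office", "outpatient",
                 "emergency", "inpatient_admissions")

.covariate_vars <- c("male", "age_band", "race_eth", .flag_vars, "bmi_class",
                     "income_k", "insured", "medicaid", "survey_wave")

#' Names of the design-vector slope terms
#'
#' Returns the covariate (non-intercept) column names of the shared design
#' matrix, in the fixed layout used throughout the package: sex, age-band
#' indicators, race/ethnicity indicators, condition flags, smoking, BMI-class
#' indicators, continuous family income, insurance indicators, and survey-wave
#' indicators.
#'
#' @return Character vector of 26 term names.
#' @export
design_terms <- function() {
  c("male",
    paste0("age_", c("35_44", "45_54", "55_64", "65_74", "75p")),
    paste0("race_", c("nh_black", "nh_other", "hispanic")),
    .flag_vars,
    "overweight", "obese",
    "income_k", "insured", "medicaid",
    paste0("wave_", c("2005_06", "2007_08", "2009_10")))
}

# Indicator-block membership, used by standardized_effect() to switch a whole
# categorical block between a target level and its reference level.
design_blocks <- function() {
  list(
    age_band    = paste0("age_", c("35_44", "45_54", "55_64", "65_74", "75p")),
    race_eth    = paste0("race_", c("nh_black", "nh_other", "hispanic")),
    bmi_class   = c("overweight", "obese"),
    survey_wave = paste0("wave_", c("2005_06", "2007_08", "2009_10"))
  )
}

check_level <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad)) {
    schema_error(sprintf("column '%s' contains values outside {%s} (e.g. '%s')",
                         what, paste(levels, collapse = ", "),
                         x[bad][1]))
  }
  x
}

check_binary <- function(x, what) {
  v <- as.numeric(x)
  if (anyNA(v) || any(v != 0 & v != 1)) {
    schema_error(sprintf("column '%s' must be 0/1 with no missing values", what))
  }
  v
}

#' Build the shared design matrix from a person table
#'
#' Expands a table of person records (as produced by
#' [generate_model_survey()] / [generate_projection_survey()]) into the fixed
#' numeric design matrix with an intercept column followed by the
#' [design_terms()] columns.
#'
#' @param records A data frame of person records with the covariate columns
#'   `male`, `age_band`, `race_eth`, the condition/smoking flags, `bmi_class`,
#'   `income_k`, `insured`, `medicaid`, `survey_wave`.
#' @return Numeric matrix with `nrow(records)` rows and 27 columns.
#' @export
build_design_matrix <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(.covariate_vars, names(records))
  if (length(miss)) {
    schema_error(paste0("records are missing covariate column(s): ",
                        paste(miss, collapse = ", ")))
  }
  n <- nrow(records)
  age  <- check_level(records$age_band, .age_levels, "age_band")
  race <- check_level(records$race_eth, .race_levels, "race_eth")
  bmi  <- check_level(records$bmi_class, .bmi_levels, "bmi_class")
  wave <- check_level(records$survey_wave, .wave_levels, "survey_wave")
  income <- as.numeric(records$income_k)
  if (anyNA(income) || any(income < 0)) {
    schema_error("column 'income_k' must be non-negative with no missing values")
  }

  X <- matrix(0, nrow = n, ncol = 27,
              dimnames = list(NULL, c("(Intercept)", design_terms())))
  X[, "(Intercept)"] <- 1
  X[, "male"] <- check_binary(records$male, "male")
  for (i in 2:6) {
    X[, paste0("age_", sub("-", "_", sub("\\+", "p", .age_levels[i])))] <-
      as.numeric(age == .age_levels[i])
  }
  for (lv in .race_levels[-1]) {
    X[, paste0("race_", lv)] <- as.numeric(race == lv)
  }
  for (v in .flag_vars) {
    X[, v] <- check_binary(records[[v]], v)
  }
  X[, "overweight"] <- as.numeric(bmi == "overweight")
  X[, "obese"]      <- as.numeric(bmi == "obese")
  X[, "income_k"]   <- income
  X[, "insured"]    <- check_binary(records$insured, "insured")
  X[, "medicaid"]   <- check_binary(records$medicaid, "medicaid")
  for (lv in .wave_levels[-1]) {
    X[, paste0("wave_", sub("-", "_", lv))] <- as.numeric(wave == lv)
  }
  X
}
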