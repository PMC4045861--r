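# Default generating coefficients for the synthetic surveys.
#
# Slopes are natural logs of odds ratios estimated on US national survey data
# (NHANES 2003-2010 risk regressions for undiagnosed diabetes / total
# prediabetes and for diagnosed prediabetes). They give the generator a
# realistic covariate-risk gradient; the intercepts are calibrated (see the
# methods vignette) so that the latent glycemic-state mix and the share of
# prediabetes that is diagnosed match the survey conditions the analysis
# assumes: roughly 54% normal / 30% prediabetes / 16% diabetes among all
# adults, with ~10% of prediabetes diagnosed and ~68.5% of diabetes diagnosed.

.or_risk <- c(
  male = 1.44,
  age_35_44 = 1.93, age_45_54 = 3.70, age_55_64 = 5.52,
  age_65_74 = 7.03, age_75p = 8.89,
  race_nh_black = 1.61, race_nh_other = 1.97, race_hispanic = 1.61,
  asthma = 1.05, arthritis = 1.02, heart_attack = 1.00, stroke = 1.06,
  cancer = 1.03, hypertension = 1.36, high_cholesterol = 1.18, cvd = 1.18,
  smoker = 1.17,
  overweight = 1.60, obese = 2.96,
  income_k = 0.998, insured = 0.81, medicaid = 1.17,
  wave_2005_06 = 1.42, wave_2007_08 = 2.43, wave_2009_10 = 2.20
)

.or_diag_predm <- c(
  male = 0.80,
  age_35_44 = 2.01, age_45_54 = 2.04, age_55_64 = 2.50,
  age_65_74 = 2.43, age_75p = 1.90,
  race_nh_black = 1.07, race_nh_other = 1.63, race_hispanic = 1.08,
  asthma = 1.51, arthritis = 1.45, heart_attack = 1.47, stroke = 1.07,
  cancer = 1.19, hypertension = 1.81, high_cholesterol = 1.56, cvd = 1.14,
  smoker = 0.72,
  overweight = 1.30, obese = 1.92,
  income_k = 0.998, insured = 1.16, medicaid = 1.11,
  wave_2005_06 = 2.86, wave_2007_08 = 3.39, wave_2009_10 = 3.79
)

named_coef <- function(intercept, slopes) {
  stopifnot(identical(names(slopes), design_terms()))
  c("(Intercept)" = unname(intercept), slopes)
}

#' Construct a set of generating ("true") coefficients
#'
#' Bundles the coefficient vectors that drive the synthetic-data generator:
#' the two polytomous equations (total prediabetes and diabetes, each versus
#' normal glycemia), a binary-logistic equation for diagnosed prediabetes
#' given latent prediabetes, and a binary-logistic equation for diagnosed
#' diabetes given latent diabetes. Every vector must be named
#' `c("(Intercept)", design_terms())` in that order.
#'
#' @param prediabetes,diabetes Polytomous coefficient vectors (reference
#'   category: normal glycemia).
#' @param diagnosed_predm Coefficients of P(diagnosed | latent prediabetes).
#' @param diagnosed_dm Coefficients of P(diagnosed | latent diabetes).
#' @return An object of class `true_coefficients`.
#' @seealso [default_true_coefficients()]
#' @export
true_coefficients <- function(prediabetes, diabetes, diagnosed_predm,
                              diagnosed_dm) {
  want <- c("(Intercept)", design_terms())
  for (nm in c("prediabetes", "diabetes", "diagnosed_predm", "diagnosed_dm")) {
    v <- get(nm)
    if (!is.numeric(v) || !identical(names(v), want)) {
      config_error(paste0("true_model$", nm),
                   "must be a numeric vector named (Intercept) + design_terms()")
    }
    if (any(!is.finite(v))) {
      config_error(paste0("true_model$", nm), "contains non-finite values")
    }
  }
  structure(list(prediabetes = prediabetes, diabetes = diabetes,
                 diagnosed_predm = diagnosed_predm,
                 diagnosed_dm = diagnosed_dm),
            class = "true_coefficients")
}

#' Default generating coefficients
#'
#' Slopes are logs of published national-survey odds ratios for the risk and
#' diagnosed-prediabetes regressions; intercepts are calibrated so the
#' generated population reproduces the assumed glycemic-state mix (about 90%
#' of prediabetes undetected, about two-thirds of diabetes diagnosed).
#' The diagnosed-diabetes equation is intercept-only by default: a
#' covariate-independent diagnosis probability leaves the covariate gradient
#' of *undiagnosed* diabetes identical to the latent-disease gradient, which
#' is what the parameter-recovery tests rely on.
#'
#' @param predm_intercept,dm_intercept Polytomous intercepts.
#' @param diag_predm_intercept Intercept of P(diagnosed | prediabetes).
#' @param p_diag_dm Marginal probability that latent diabetes is diagnosed.
#' @return A [true_coefficients()] object.
#' @export
default_true_coefficients <- function(predm_intercept = -2.954,
                                      dm_intercept = -3.611,
                                      diag_predm_intercept = -4.996,
                                      p_diag_dm = 0.685) {
  zero <- setNames(rep(0, length(design_terms())), design_terms())
  true_coefficients(
    prediabetes     = named_coef(predm_intercept, log(.or_risk)),
    diabetes        = named_coef(dm_intercept, log(.or_risk)),
    diagnosed_predm = named_coef(diag_predm_intercept, log(.or_diag_predm)),
    diagnosed_dm    = named_coef(stats::qlogis(p_diag_dm), zero)
  )
}

#' All-zero generating coefficients
#'
#' Convenience constructor for degenerate scenarios (symmetric latent states,
#' coin-flip diagnosis) used in tests and examples.
#'
#' @inheritParams default_true_coefficients
#' @param diag_dm_intercept Intercept of P(diagnosed | diabetes).
#' @return A [true_coefficients()] object with all slopes zero.
#' @export
flat_true_coefficients <- function(predm_intercept = 0, dm_intercept = 0,
                                   diag_predm_intercept = 0,
                                   diag_dm_intercept = 0) {
  zero <- setNames(rep(0, length(design_terms())), design_terms())
  true_coefficients(
    prediabetes     = named_coef(predm_intercept, zero),
    diabetes        = named_coef(dm_intercept, zero),
    diagnosed_predm = named_coef(diag_predm_intercept, zero),
    diagnosed_dm    = named_coef(diag_dm_intercept, zero)
  )
}
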