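# Screening-guideline rule engine.
#
# A screening rule maps each person record to (eligible, annual screening
# fraction, triggered criteria). Fractions are applied as deterministic
# expected-value multipliers: a fraction of 1/3 means the rule screens the
# person with annual probability one-in-three (three-year re-screening
# cycle), so the person contributes one third of their sampling weight to
# the screened population in a single-year projection.

#' Construct a screening rule
#'
#' @param name Rule identifier.
#' @param evaluate Function taking a person table and returning a data frame
#'   with columns `eligible` (logical), `fraction` (numeric in \[0, 1\], 0
#'   whenever not eligible) and `criteria` (character description of the
#'   clauses that fired).
#' @return An object of class `screening_rule`.
#' @export
screening_rule <- function(name, evaluate) {
  stopifnot(is.character(name), is.function(evaluate))
  structure(list(name = name, evaluate = evaluate), class = "screening_rule")
}

#' Evaluate a screening rule on person records
#'
#' @param rule A [screening_rule()].
#' @param records Person table.
#' @return Tibble with columns `eligible`, `fraction`, `criteria`; the
#'   invariants `fraction > 0 => eligible` and `!eligible => fraction == 0`
#'   are enforced.
#' @export
evaluate_rule <- function(rule, records) {
  if (!inherits(rule, "screening_rule")) {
    schema_error("'rule' must be a screening_rule object")
  }
  out <- tibble::as_tibble(rule$evaluate(records))
  if (!all(c("eligible", "fraction") %in% names(out)) ||
      nrow(out) != nrow(records)) {
    schema_error(sprintf("rule '%s' returned a malformed evaluation", rule$name))
  }
  if (any(out$fraction < 0 | out$fraction > 1) ||
      any(out$fraction > 0 & !out$eligible) ||
      any(!out$eligible & out$fraction != 0)) {
    schema_error(sprintf("rule '%s' violated the eligibility/fraction contract",
                         rule$name))
  }
  out
}

require_cols <- function(records, cols, rule) {
  miss <- setdiff(cols, names(records))
  if (length(miss)) {
    missing_data_error(sprintf("rule '%s' requires column(s): %s",
                               rule, paste(miss, collapse = ", ")))
  }
  for (cc in cols) {
    if (anyNA(records[[cc]])) {
      missing_data_error(sprintf("rule '%s': column '%s' has missing values",
                                 rule, cc))
    }
  }
}

#' USPSTF screening rule (2008-era)
#'
#' Screens adults with sustained hypertension. The projection survey carries
#' no measured blood pressure, so the diagnosed-hypertension indicator is
#' used as the proxy for "sustained blood pressure > 135/80 mm Hg".
#' Eligible persons are screened with fraction 1.
#'
#' @return A [screening_rule()].
#' @export
uspstf_rule <- function() {
  screening_rule("uspstf", function(records) {
    require_cols(records, "hypertension", "uspstf")
    el <- as.numeric(records$hypertension) == 1
    tibble::tibble(eligible = el,
                   fraction = as.numeric(el),
                   criteria = ifelse(el, "hypertension", ""))
  })
}

#' Default ADA "additional risk factor" predicates
#'
#' The risk factors from the ADA criteria that are observable in the
#' projection survey: diagnosed hypertension, high cholesterol,
#' cardiovascular disease, and membership of a high-risk (non-white)
#' racial/ethnic population. Family history, physical inactivity, polycystic
#' ovarian syndrome, gestational diabetes and acanthosis nigricans are not
#' recorded in either survey and are therefore omitted.
#'
#' @return Named list of predicate functions (person table -> logical).
#' @export
default_ada_risk_factors <- function() {
  list(
    hypertension = function(r) as.numeric(r$hypertension) == 1,
    high_cholesterol = function(r) as.numeric(r$high_cholesterol) == 1,
    cvd = function(r) as.numeric(r$cvd) == 1,
    minority_race = function(r) as.character(r$race_eth) != "nh_white"
  )
}

#' ADA screening rule
#'
#' Screens everyone age 45 and older (band-level: bands 45-54 and above),
#' plus overweight or obese adults of any age with at least one additional
#' risk factor. A person eligible *only* through age (not overweight/obese
#' with a risk factor) is re-screened on a three-year cycle and so is
#' screened with annual fraction 1/3; anyone on the weight-plus-risk-factor
#' path is screened with fraction 1.
#'
#' @param risk_factors Named list of predicate functions counting as
#'   "additional risk factors"; see [default_ada_risk_factors()].
#' @return A [screening_rule()].
#' @export
ada_rule <- function(risk_factors = default_ada_risk_factors()) {
  stopifnot(is.list(risk_factors), length(risk_factors) >= 1)
  screening_rule("ada", function(records) {
    require_cols(records, c("age_band", "bmi_class"), "ada")
    age <- check_level(records$age_band, .age_levels, "age_band")
    bmi <- check_level(records$bmi_class, .bmi_levels, "bmi_class")
    age45p <- age %in% .age_levels[3:6]
    excess <- bmi %in% c("overweight", "obese")
    any_rf <- Reduce(`|`, lapply(risk_factors, function(f) {
      v <- f(records)
      if (anyNA(v)) missing_data_error("rule 'ada': risk-factor predicate returned NA")
      v
    }))
    weight_path <- excess & any_rf
    eligible <- age45p | weight_path
    tibble::tibble(
      eligible = eligible,
      fraction = ifelse(weight_path, 1, ifelse(age45p, 1 / 3, 0)),
      criteria = ifelse(weight_path & age45p, "age+weight_risk",
                        ifelse(weight_path, "weight_risk",
                               ifelse(age45p, "age", "")))
    )
  })
}

#' Partition records by eligibility under two rules
#'
#' Assigns every record to one of four cells (both rules, rule A only,
#' rule B only, neither) and reports record counts, plain-weighted
#' population totals (eligibility accounting) and fraction-weighted screened
#' totals under each rule (screened-population accounting).
#'
#' @param records Person table.
#' @param rule_a,rule_b [screening_rule()] objects.
#' @param weight_col Weight column name.
#' @return Tibble with one row per cell: `cell`, `n`, `population`,
#'   `screened_a`, `screened_b`.
#' @export
rule_overlap <- function(records, rule_a, rule_b, weight_col = "weight") {
  ev_a <- evaluate_rule(rule_a, records)
  ev_b <- evaluate_rule(rule_b, records)
  w <- as.numeric(records[[weight_col]])
  cell <- factor(ifelse(ev_a$eligible & ev_b$eligible, "both",
                        ifelse(ev_a$eligible, "a_only",
                               ifelse(ev_b$eligible, "b_only", "neither"))),
                 levels = c("both", "a_only", "b_only", "neither"))
  agg <- function(x) as.vector(tapply(x, cell, sum, default = 0))
  n_cell <- as.vector(table(cell))
  tibble::tibble(
    cell = levels(cell),
    n = n_cell,
    population = agg(w),
    screened_a = agg(w * ev_a$fraction),
    screened_b = agg(w * ev_b$fraction)
  )
}
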