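# Expected screened / detected population totals.
#
# Every total is an expectation: a record with sampling weight w, screening
# fraction f and undetected-condition probability p contributes w*f persons
# to the screened population and w*f*s*p expected detected cases (s is the
# national-calibration factor). Detected counts are never integerized;
# rounding happens only at presentation time (half away from zero).

#' Assemble a projection result from population totals
#'
#' The totals-level core of [project()]: given a screened-population total
#' and expected detected-case totals it derives the screening-efficiency
#' ratios (people screened per diabetes case detected, and per case of
#' either condition detected). It can be applied directly to published
#' population totals to reproduce printed efficiency statistics.
#'
#' @param screened_total Persons screened.
#' @param detected_dm Expected undiagnosed-diabetes cases detected.
#' @param detected_predm Expected undetected-prediabetes cases detected.
#' @return An object of class `projection_result`: a list with the three
#'   totals plus `screened_per_dm_case` and `screened_per_any_case`
#'   (`NaN` with a warning when no cases are detected).
#' @export
projection_result <- function(screened_total, detected_dm, detected_predm) {
  if (any(c(screened_total, detected_dm, detected_predm) < 0)) {
    schema_error("projection totals must be non-negative")
  }
  if (detected_dm + detected_predm <= 0) {
    warning("no detected cases: screening-efficiency ratios are undefined (NaN)")
  }
  ratio <- function(num, den) if (den > 0) num / den else NaN
  structure(list(
    screened_total = screened_total,
    detected_dm = detected_dm,
    detected_predm = detected_predm,
    screened_per_dm_case = ratio(screened_total, detected_dm),
    screened_per_any_case = ratio(screened_total, detected_dm + detected_predm)
  ), class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    paste0("Screening projection\n",
           "  screened:            %s persons\n",
           "  detected diabetes:   %s\n",
           "  detected prediabetes:%s\n",
           "  screened per diabetes case: %.1f\n",
           "  screened per any case:      %.1f\n"),
    format(round_half_up(x$screened_total), big.mark = ","),
    format(round_half_up(x$detected_dm), big.mark = ","),
    format(round_half_up(x$detected_predm), big.mark = ","),
    x$screened_per_dm_case, x$screened_per_any_case))
  invisible(x)
}

check_alignment <- function(records, profiles) {
  if (nrow(records) != nrow(profiles)) {
    schema_error("records and risk profiles are not aligned (different row counts)")
  }
  need <- c("p_undiag_dm", "p_undet_predm")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    schema_error(paste0("profiles are missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
}

#' Project screened and detected population totals under a rule
#'
#' Sums `weight * fraction` over rule-eligible records for the screened
#' total, and `weight * fraction * scale * probability` for the expected
#' detected cases of each condition.
#'
#' @param records Person table with weights and the rule's covariates.
#' @param profiles Aligned risk-profile tibble from [predict_risk()].
#' @param rule A [screening_rule()].
#' @param scale National-calibration factor applied to the detected-case
#'   probabilities (not to the screened total); see [calibrate_scale()].
#' @param weight_col Weight column name.
#' @return A [projection_result()].
#' @export
#' @examples
#' # one eligible person, weight 1000, p(undetected predm) 0.3, p(undiag dm) 0.1
#' rec <- tibble::tibble(weight = 1000, hypertension = 1)
#' prof <- tibble::tibble(p_undet_predm = 0.3, p_undiag_dm = 0.1)
#' project(rec, prof, uspstf_rule())  # 1000 screened, 300 predm, 100 dm
project <- function(records, profiles, rule, scale = 1, weight_col = "weight") {
  check_alignment(records, profiles)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    schema_error("'scale' must be a positive scalar")
  }
  ev <- evaluate_rule(rule, records)
  w <- as.numeric(records[[weight_col]])
  wf <- w * ev$fraction
  projection_result(
    screened_total = sum(wf),
    detected_dm = sum(wf * scale * profiles$p_undiag_dm),
    detected_predm = sum(wf * scale * profiles$p_undet_predm)
  )
}

subgroup_factor <- function(records, grouping, weight_col = "weight") {
  w <- as.numeric(records[[weight_col]])
  switch(grouping,
    age = {
      age <- check_level(records$age_band, .age_levels, "age_band")
      factor(ifelse(age %in% .age_levels[1:2], "<45",
                    ifelse(age == "45-54", "45-54",
                           ifelse(age == "55-64", "55-64", "65+"))),
             levels = c("<45", "45-54", "55-64", "65+"))
    },
    sex = factor(ifelse(as.numeric(records$male) == 1, "men", "women"),
                 levels = c("men", "women")),
    race_eth = factor(check_level(records$race_eth, .race_levels, "race_eth"),
                      levels = .race_levels),
    bmi_class = factor(check_level(records$bmi_class, .bmi_levels, "bmi_class"),
                       levels = .bmi_levels),
    income_quartile = {
      q <- weighted_quantile(records$income_k, w, c(0.25, 0.5, 0.75))
      cut(records$income_k, breaks = c(-Inf, q, Inf),
          labels = c("Q1", "Q2", "Q3", "Q4"))
    },
    insured = factor(ifelse(as.numeric(records$insured) == 1,
                            "insured", "uninsured"),
                     levels = c("insured", "uninsured")),
    schema_error(sprintf("unknown grouping '%s'", grouping))
  )
}

#' Subgroup projection table
#'
#' Splits the projection totals by a categorical grouping; each record falls
#' in exactly one level, so rows sum to the overall totals.
#'
#' @inheritParams project
#' @param grouping One of `"age"` (collapsed to <45 / 45-54 / 55-64 / 65+),
#'   `"sex"`, `"race_eth"`, `"bmi_class"`, `"income_quartile"` (weighted
#'   quartiles of the projection population), `"insured"`.
#' @return Tibble with one row per level: `level`, `screened_total`,
#'   `detected_dm`, `detected_predm`.
#' @export
subgroup_table <- function(records, profiles, rule, grouping, scale = 1,
                           weight_col = "weight") {
  check_alignment(records, profiles)
  g <- subgroup_factor(records, grouping, weight_col)
  ev <- evaluate_rule(rule, records)
  wf <- as.numeric(records[[weight_col]]) * ev$fraction
  agg <- function(x) as.vector(tapply(x, g, sum, default = 0))
  tibble::tibble(
    level = levels(g),
    screened_total = agg(wf),
    detected_dm = agg(wf * scale * profiles$p_undiag_dm),
    detected_predm = agg(wf * scale * profiles$p_undet_predm)
  )
}

#' Percent more cases detected under one rule than another
#'
#' Totals-level core of [compare_rules()]: `100 * (a / b - 1)` computed from
#' unrounded detected totals for each condition.
#'
#' @param result_a,result_b [projection_result()] objects.
#' @return List with `pct_more_dm` and `pct_more_predm`.
#' @export
detection_gain <- function(result_a, result_b) {
  list(
    pct_more_dm = 100 * (result_a$detected_dm / result_b$detected_dm - 1),
    pct_more_predm = 100 * (result_a$detected_predm / result_b$detected_predm - 1)
  )
}

#' Percent of a national case total covered by a rule's detections
#'
#' @param detected Expected detected cases under the rule.
#' @param national_total National case total for the condition.
#' @return Percentage (numeric scalar).
#' @export
coverage_percent <- function(detected, national_total) {
  if (national_total <= 0) degenerate_data_error("national total must be positive")
  100 * detected / national_total
}

#' Compare two screening rules on the same population
#'
#' Projects both rules, partitions the population by eligibility overlap
#' (with fraction-weighted screened and expected detected totals per cell
#' under each rule), and reports how many percent more cases of each
#' condition rule A detects than rule B.
#'
#' @inheritParams project
#' @param rule_a,rule_b [screening_rule()] objects.
#' @return List of class `rule_comparison` with `result_a`, `result_b`,
#'   `overlap` (cell table with per-cell detected totals), `pct_more_dm`,
#'   `pct_more_predm`.
#' @export
compare_rules <- function(records, profiles, rule_a, rule_b, scale = 1,
                          weight_col = "weight") {
  check_alignment(records, profiles)
  res_a <- project(records, profiles, rule_a, scale, weight_col)
  res_b <- project(records, profiles, rule_b, scale, weight_col)
  ov <- rule_overlap(records, rule_a, rule_b, weight_col)

  ev_a <- evaluate_rule(rule_a, records)
  ev_b <- evaluate_rule(rule_b, records)
  w <- as.numeric(records[[weight_col]])
  cell <- factor(ifelse(ev_a$eligible & ev_b$eligible, "both",
                        ifelse(ev_a$eligible, "a_only",
                               ifelse(ev_b$eligible, "b_only", "neither"))),
                 levels = c("both", "a_only", "b_only", "neither"))
  agg <- function(x) as.vector(tapply(x, cell, sum, default = 0))
  ov$detected_dm_a <- agg(w * ev_a$fraction * scale * profiles$p_undiag_dm)
  ov$detected_dm_b <- agg(w * ev_b$fraction * scale * profiles$p_undiag_dm)
  ov$detected_predm_a <- agg(w * ev_a$fraction * scale * profiles$p_undet_predm)
  ov$detected_predm_b <- agg(w * ev_b$fraction * scale * profiles$p_undet_predm)

  gain <- detection_gain(res_a, res_b)
  structure(list(result_a = res_a, result_b = res_b, overlap = ov,
                 pct_more_dm = gain$pct_more_dm,
                 pct_more_predm = gain$pct_more_predm),
            class = "rule_comparison")
}
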