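# Health-care utilisation by predicted-risk stratum and primary-care
# screening opportunities.

#' Define risk bands over a predicted probability
#'
#' Bands are half-open `[lo, hi)` with the last band closed above at 1,
#' matching the "0.05 to <0.10" reading of published utilisation tables.
#'
#' @param variable `"p_undiag_dm"` or `"p_undet_predm"`.
#' @param breakpoints Strictly ascending probabilities in (0, 1); empty for a
#'   single all-inclusive band.
#' @return An object of class `risk_band_spec`.
#' @export
risk_bands <- function(variable = c("p_undiag_dm", "p_undet_predm"),
                       breakpoints = numeric(0)) {
  variable <- match.arg(variable)
  if (length(breakpoints)) {
    if (any(breakpoints <= 0 | breakpoints >= 1) ||
        any(diff(breakpoints) <= 0)) {
      schema_error("breakpoints must be strictly ascending and inside (0, 1)")
    }
  }
  labels <- if (length(breakpoints) == 0) {
    "all"
  } else {
    k <- length(breakpoints)
    c(paste0("<", breakpoints[1]),
      if (k > 1) paste0(breakpoints[-k], " to <", breakpoints[-1]),
      paste0(">=", breakpoints[k]))
  }
  structure(list(variable = variable, breakpoints = breakpoints,
                 labels = labels),
            class = "risk_band_spec")
}

#' Weighted visit patterns by predicted-risk band
#'
#' Places each record in exactly one band by its predicted probability and
#' reports the weighted population and weighted mean annual visits per care
#' setting plus the total.
#'
#' @param records Person table carrying the five visit-count columns.
#' @param profiles Aligned risk-profile tibble.
#' @param spec A [risk_bands()] specification.
#' @param weight_col Weight column name.
#' @return Tibble with one row per band: `band`, `population`, the five
#'   per-setting mean-visit columns, and `total`.
#' @export
utilization_by_band <- function(records, profiles, spec,
                                weight_col = "weight") {
  if (!inherits(spec, "risk_band_spec")) {
    schema_error("'spec' must be a risk_band_spec object")
  }
  check_alignment(records, profiles)
  miss <- setdiff(.visit_vars, names(records))
  if (length(miss)) {
    missing_data_error(paste0("records are missing visit column(s): ",
                              paste(miss, collapse = ", ")))
  }
  p <- profiles[[spec$variable]]
  idx <- findInterval(p, c(-Inf, spec$breakpoints))
  band <- factor(spec$labels[idx], levels = spec$labels)
  w <- as.numeric(records[[weight_col]])

  pop <- as.vector(tapply(w, band, sum, default = 0))
  out <- tibble::tibble(band = spec$labels, population = pop)
  total <- rep(0, length(spec$labels))
  for (v in .visit_vars) {
    num <- as.vector(tapply(w * as.numeric(records[[v]]), band, sum,
                            default = 0))
    m <- ifelse(pop > 0, num / pop, NA_real_)
    out[[v]] <- m
    total <- total + ifelse(is.na(m), 0, m)
  }
  out$total <- ifelse(pop > 0, total, NA_real_)
  out
}

#' Summarise primary-care screening opportunities from totals
#'
#' Totals-level core of [primary_care_opportunity()]: derives the percent of
#' the rule's screened population with at least one primary-care visit and
#' the percent of the rule's detectable cases of each condition reachable
#' during those visits. Can be applied directly to published totals.
#'
#' @param screened_total Rule's screened-population total.
#' @param pc_screened Screened persons with >= 1 primary-care office visit.
#' @param detected_dm_total,detected_dm_pc Expected detectable
#'   undiagnosed-diabetes cases overall and among primary-care visitors.
#' @param detected_predm_total,detected_predm_pc Same for undetected
#'   prediabetes.
#' @return An object of class `opportunity_report`: the six totals plus
#'   `pct_pc_visit`, `pct_dm_reachable`, `pct_predm_reachable`.
#' @export
opportunity_summary <- function(screened_total, pc_screened,
                                detected_dm_total, detected_dm_pc,
                                detected_predm_total, detected_predm_pc) {
  vals <- c(screened_total, pc_screened, detected_dm_total, detected_dm_pc,
            detected_predm_total, detected_predm_pc)
  if (any(vals < 0)) schema_error("opportunity totals must be non-negative")
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  structure(list(
    screened_total = screened_total,
    pc_screened = pc_screened,
    detected_dm_total = detected_dm_total,
    detected_dm_pc = detected_dm_pc,
    detected_predm_total = detected_predm_total,
    detected_predm_pc = detected_predm_pc,
    pct_pc_visit = pct(pc_screened, screened_total),
    pct_dm_reachable = pct(detected_dm_pc, detected_dm_total),
    pct_predm_reachable = pct(detected_predm_pc, detected_predm_total)
  ), class = "opportunity_report")
}

#' @export
print.opportunity_report <- function(x, ...) {
  cat(sprintf(
    paste0("Primary-care screening opportunity\n",
           "  screened population:          %s\n",
           "  with >=1 primary-care visit:  %s (%.1f%%)\n",
           "  detectable diabetes reachable:    %.0f%%\n",
           "  detectable prediabetes reachable: %.0f%%\n"),
    format(round_half_up(x$screened_total), big.mark = ","),
    format(round_half_up(x$pc_screened), big.mark = ","),
    x$pct_pc_visit,
    round_half_up(x$pct_dm_reachable),
    round_half_up(x$pct_predm_reachable)))
  invisible(x)
}

#' Primary-care screening opportunities under a rule
#'
#' Among rule-eligible records (fraction-weighted), reports how many
#' screened persons had at least one primary-care office visit during the
#' year, what share of the screened population that is, the expected
#' detectable cases among those visitors, and the share of the rule's total
#' detectable cases reachable through primary care. "At least one
#' primary-care visit" uses the primary-care office-visit count only.
#'
#' @inheritParams project
#' @return An `opportunity_report`; see [opportunity_summary()].
#' @export
primary_care_opportunity <- function(records, profiles, rule, scale = 1,
                                     weight_col = "weight") {
  check_alignment(records, profiles)
  if (!"primary_care_office" %in% names(records) ||
      anyNA(records$primary_care_office)) {
    missing_data_error("records must carry complete primary_care_office visit counts")
  }
  ev <- evaluate_rule(rule, records)
  w <- as.numeric(records[[weight_col]])
  wf <- w * ev$fraction
  pc <- as.numeric(records$primary_care_office) >= 1
  opportunity_summary(
    screened_total = sum(wf),
    pc_screened = sum(wf[pc]),
    detected_dm_total = sum(wf * scale * profiles$p_undiag_dm),
    detected_dm_pc = sum((wf * scale * profiles$p_undiag_dm)[pc]),
    detected_predm_total = sum(wf * scale * profiles$p_undet_predm),
    detected_predm_pc = sum((wf * scale * profiles$p_undet_predm)[pc])
  )
}
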