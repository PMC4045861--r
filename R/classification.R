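# Lab-threshold classification and sample exclusions.
#
# Clinical cut-points (ADA diagnostic criteria):
#   diabetes     HbA1c >= 6.5 %   | FPG >= 126 mg/dL  | 2-h OGTT >= 200 mg/dL
#   prediabetes  HbA1c 5.7-6.4 %  | FPG 100-125 mg/dL | 2-h OGTT 140-199 mg/dL
# A person is in the diabetes range if ANY included test is; otherwise in the
# prediabetes range if any included test is; otherwise normal. Non-integer
# values between the printed prediabetes upper bound and the diabetes
# cut-point (e.g. FPG 125.5) fall in the lower category: intervals are
# half-open, anchored at the diabetes cut-points.

.status_levels <- c("normal", "undetected_prediabetes", "diagnosed_prediabetes",
                    "undiagnosed_diabetes", "diagnosed_diabetes")

.lab_cuts <- list(
  hba1c = c(predm = 5.7, dm = 6.5),
  fpg   = c(predm = 100, dm = 126),
  ogtt  = c(predm = 140, dm = 200)
)

#' Classify a glycemic lab panel
#'
#' Applies the diagnostic thresholds to up to three test values and returns
#' the lab category. All arguments are vectorised; `NA` means the test was
#' not performed. Only tests named in `tests` are considered, so the same
#' panel can be re-classified under a restricted test subset for sensitivity
#' analyses.
#'
#' @param hba1c Hemoglobin A1c, percent.
#' @param fpg Fasting plasma glucose, mg/dL.
#' @param ogtt 2-hour oral glucose tolerance test, mg/dL.
#' @param tests Non-empty subset of `c("hba1c", "fpg", "ogtt")` to use.
#' @return Character vector in `c("normal", "prediabetes", "diabetes")`.
#' @export
#' @examples
#' classify_lab(hba1c = 6.5)             # "diabetes"
#' classify_lab(hba1c = 5.5, fpg = 130)  # "diabetes" (any-test rule)
#' classify_lab(hba1c = 5.7, fpg = 99)   # "prediabetes"
classify_lab <- function(hba1c = NA_real_, fpg = NA_real_, ogtt = NA_real_,
                         tests = c("hba1c", "fpg", "ogtt")) {
  if (length(tests) == 0 || !all(tests %in% c("hba1c", "fpg", "ogtt"))) {
    schema_error("'tests' must be a non-empty subset of hba1c, fpg, ogtt")
  }
  n <- max(length(hba1c), length(fpg), length(ogtt))
  vals <- list(hba1c = rep_len(as.numeric(hba1c), n),
               fpg   = rep_len(as.numeric(fpg), n),
               ogtt  = rep_len(as.numeric(ogtt), n))
  for (t in setdiff(c("hba1c", "fpg", "ogtt"), tests)) {
    vals[[t]] <- rep(NA_real_, n)
  }
  present <- Reduce(`|`, lapply(vals, function(v) !is.na(v)))
  if (any(!present)) {
    missing_data_error(
      "cannot classify: no included lab test value present for some records")
  }
  any_at_least <- function(cut_name) {
    Reduce(`|`, lapply(names(vals), function(t) {
      v <- vals[[t]]
      !is.na(v) & v >= .lab_cuts[[t]][[cut_name]]
    }))
  }
  ifelse(any_at_least("dm"), "diabetes",
         ifelse(any_at_least("predm"), "prediabetes", "normal"))
}

#' Assign a five-level glycemic status to survey records
#'
#' Combines the lab category with the self-reported diagnosis flags:
#' a diagnosed-diabetes flag dominates everything; otherwise the lab
#' category is crossed with the diagnosed-prediabetes flag (lab prediabetes
#' with the flag is `diagnosed_prediabetes`, without it
#' `undetected_prediabetes`; lab diabetes without a diabetes diagnosis is
#' `undiagnosed_diabetes` regardless of a prediabetes diagnosis).
#'
#' @param records Data frame with lab columns `hba1c`, `fpg`, `ogtt_2h` and
#'   flags `diagnosed_diabetes`, `diagnosed_prediabetes`.
#' @param tests Lab tests to include, as in [classify_lab()].
#' @return Character vector over the five status levels.
#' @export
assign_status <- function(records, tests = c("hba1c", "fpg", "ogtt")) {
  dd <- as.integer(records$diagnosed_diabetes)
  dp <- as.integer(records$diagnosed_prediabetes)
  if (anyNA(dd) || anyNA(dp)) {
    missing_data_error("diagnosis flags must be present (0/1) for all records")
  }
  n <- nrow(records)
  status <- rep(NA_character_, n)
  status[dd == 1] <- "diagnosed_diabetes"
  todo <- dd != 1
  if (any(todo)) {
    lab <- classify_lab(records$hba1c[todo], records$fpg[todo],
                        records$ogtt_2h[todo], tests = tests)
    status[todo] <- ifelse(
      lab == "diabetes", "undiagnosed_diabetes",
      ifelse(lab == "prediabetes",
             ifelse(dp[todo] == 1, "diagnosed_prediabetes",
                    "undetected_prediabetes"),
             "normal"))
  }
  status
}

#' Collapse five-level status to the three modelled outcomes
#'
#' The risk model's outcome has three values: normal, prediabetes (diagnosed
#' or undetected), and undiagnosed diabetes. Diagnosed-diabetes records must
#' have been excluded before modelling.
#'
#' @param status Character/factor vector over the five status levels.
#' @return Factor with levels `normal`, `prediabetes`, `undiag_dm`.
#' @export
collapse_status <- function(status) {
  status <- as.character(status)
  if (any(status == "diagnosed_diabetes")) {
    degenerate_data_error(
      "diagnosed-diabetes records must be excluded before model fitting")
  }
  bad <- !(status %in% .status_levels)
  if (any(bad)) {
    schema_error(sprintf("unknown status value '%s'", status[bad][1]))
  }
  out <- ifelse(status == "normal", "normal",
                ifelse(status == "undiagnosed_diabetes", "undiag_dm",
                       "prediabetes"))
  factor(out, levels = c("normal", "prediabetes", "undiag_dm"))
}

#' Apply the analysis exclusion criteria
#'
#' Removes records of women pregnant at interview and records with diagnosed
#' diabetes, preserving input order. A record that is both pregnant and
#' diagnosed is counted once, attributed to pregnancy (fixed attribution
#' order for reproducible logs).
#'
#' @param records Data frame with `pregnant` and `diagnosed_diabetes` columns.
#' @return List with `kept` (the filtered table), `excluded_pregnant` and
#'   `excluded_diagnosed_dm` counts.
#' @export
apply_exclusions <- function(records) {
  preg <- as.integer(records$pregnant) == 1
  diag <- as.integer(records$diagnosed_diabetes) == 1
  list(
    kept = records[!preg & !diag, , drop = FALSE],
    excluded_pregnant = sum(preg),
    excluded_diagnosed_dm = sum(diag & !preg)
  )
}
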