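# Pairwise concordance diagnostics (percent concordant / discordant / tied,
# Somers' D, c-statistic) computed by an O(n log n) rank-based algorithm
# rather than explicit pair enumeration.
#
# Over all (positive, negative) outcome pairs: a pair is concordant if the
# positive record has the strictly higher score, discordant if strictly
# lower, tied if the scores are exactly equal (no rounding before
# comparison). Then Somers' D = (C - D) / P and c = (C + T/2) / P.

#' Concordance statistics for predicted scores against a binary outcome
#'
#' @param scores Numeric predicted scores (higher = more likely positive).
#' @param outcomes Binary outcome (0/1 or logical).
#' @return An object of class `concordance_report`: a list with
#'   `pct_concordant`, `pct_discordant`, `pct_tied` (percentages summing to
#'   100), `n_pairs`, `somers_d`, `c_statistic`.
#' @export
#' @examples
#' concordance(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$c_statistic  # 1
concordance <- function(scores, outcomes) {
  y <- as.numeric(outcomes)
  if (length(y) != length(scores) || anyNA(y) || anyNA(scores) ||
      any(y != 0 & y != 1)) {
    schema_error("scores and 0/1 outcomes must be aligned and complete")
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    degenerate_data_error("concordance needs at least one positive and one negative outcome")
  }
  n_pairs <- as.double(n1) * as.double(n0)

  r <- rank(scores, ties.method = "average")
  u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2     # = C + T/2 (Mann-Whitney)

  by_value <- rowsum(cbind(pos = y, neg = 1 - y), group = scores)
  n_tied <- sum(as.double(by_value[, "pos"]) * as.double(by_value[, "neg"]))

  n_conc <- u - n_tied / 2
  n_disc <- n_pairs - n_conc - n_tied

  structure(list(
    pct_concordant = 100 * n_conc / n_pairs,
    pct_discordant = 100 * n_disc / n_pairs,
    pct_tied = 100 * n_tied / n_pairs,
    n_pairs = n_pairs,
    somers_d = (n_conc - n_disc) / n_pairs,
    c_statistic = (n_conc + n_tied / 2) / n_pairs
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    paste0("Concordance over %s positive-negative pairs\n",
           "  concordant %.1f%%  discordant %.1f%%  tied %.1f%%\n",
           "  Somers' D %.3f   c-statistic %.3f\n"),
    format(x$n_pairs, big.mark = ","),
    x$pct_concordant, x$pct_discordant, x$pct_tied,
    x$somers_d, x$c_statistic))
  invisible(x)
}

#' Calibration scale factor against national totals
#'
#' Computes the single multiplicative factor `s = sum(national_targets) /
#' sum(predicted_totals)` that, applied to every person's predicted
#' undiagnosed-diabetes and undetected-prediabetes probabilities, makes the
#' summed national totals match external (e.g. CDC) estimates.
#'
#' @param predicted_totals Numeric vector of predicted national totals (one
#'   element per condition).
#' @param national_targets Numeric vector of target totals, same length.
#' @return Scale factor (scalar).
#' @export
#' @examples
#' calibrate_scale(88.2, 86.0)  # about 0.975
calibrate_scale <- function(predicted_totals, national_targets) {
  if (length(predicted_totals) != length(national_targets)) {
    schema_error("predicted and target totals must have the same length")
  }
  tot <- sum(predicted_totals)
  if (!is.finite(tot) || tot <= 0) {
    degenerate_data_error("predicted totals must sum to a positive number")
  }
  sum(national_targets) / tot
}

#' Rescale a risk-profile table by a calibration factor
#'
#' Multiplies `p_undiag_dm` and `p_undet_predm` by `s`, leaving the other
#' profile columns untouched.
#'
#' @param profiles A tibble from [predict_risk()].
#' @param s Positive scale factor.
#' @return The rescaled profile tibble.
#' @export
scale_profiles <- function(profiles, s) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0) {
    schema_error("'s' must be a positive scalar")
  }
  profiles$p_undiag_dm <- profiles$p_undiag_dm * s
  profiles$p_undet_predm <- profiles$p_undet_predm * s
  profiles
}
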