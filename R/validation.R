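# Split-sample validation: fit the risk model on a random half of the
# model survey, predict the held-out half, and compare summed predicted
# probabilities with observed weighted case counts by age band.

#' Seeded exact half-split indices
#'
#' Randomly permutes `1:n` and assigns the first half to subset A; with odd
#' `n` the extra record goes to A. The split is deterministic given the
#' seed, the two halves are disjoint and their union is `1:n`.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @return List with integer index vectors `a` and `b`.
#' @export
split_half_indices <- function(n, seed) {
  if (n < 2) degenerate_data_error("need at least 2 records to split")
  perm <- with_preserved_rng(seed, sample.int(n))
  n_a <- ceiling(n / 2)
  list(a = sort(perm[seq_len(n_a)]), b = sort(perm[-seq_len(n_a)]))
}

#' Split-sample validation of the polytomous risk model
#'
#' Splits the classified model survey in half, fits the polytomous model on
#' half A, predicts half B, and tabulates observed versus predicted weighted
#' totals of total prediabetes and undiagnosed diabetes by age band. Both
#' halves are also fitted separately to summarise coefficient stability
#' (maximum and mean absolute slope difference).
#'
#' @param records Classified model-survey table (exclusions applied, with a
#'   `status` column over the remaining four status levels).
#' @param seed Integer seed for the split.
#' @param status_col,weight_col Column names.
#' @return List of class `validation_report`: `table` (per age band:
#'   observed and predicted weighted totals and predicted/observed ratios
#'   for each condition), `half_sizes`, `coef_max_abs_diff`,
#'   `coef_mean_abs_diff`, and the half-A fit.
#' @export
split_sample_validate <- function(records, seed, status_col = "status",
                                  weight_col = "weight") {
  n <- nrow(records)
  idx <- split_half_indices(n, seed)
  half_a <- records[idx$a, , drop = FALSE]
  half_b <- records[idx$b, , drop = FALSE]

  y_a <- collapse_status(half_a[[status_col]])
  y_b <- collapse_status(half_b[[status_col]])
  if (any(table(y_a) < 2) || any(table(y_b) < 2)) {
    degenerate_data_error(
      "each half must contain at least 2 records per outcome category")
  }

  fit_a <- fit_polytomous(half_a, status = status_col,
                          weight_col = weight_col)
  fit_b <- fit_polytomous(half_b, status = status_col,
                          weight_col = weight_col)

  slopes <- function(f) f$coef[rownames(f$coef) != "(Intercept)", ]
  dmat <- abs(slopes(fit_a) - slopes(fit_b))

  # predict half B from the half-A fit (polytomous probabilities only)
  X <- build_design_matrix(half_b)
  P <- softmax3(drop(X %*% fit_a$coef[, "prediabetes"]),
                drop(X %*% fit_a$coef[, "undiag_dm"]))
  w <- as.numeric(half_b[[weight_col]])
  band <- factor(check_level(half_b$age_band, .age_levels, "age_band"),
                 levels = .age_levels)
  agg <- function(x) as.vector(tapply(x, band, sum, default = 0))

  obs_predm <- agg(w * (y_b == "prediabetes"))
  obs_dm <- agg(w * (y_b == "undiag_dm"))
  pred_predm <- agg(w * P[, 2])
  pred_dm <- agg(w * P[, 3])

  tab <- tibble::tibble(
    age_band = .age_levels,
    observed_predm = obs_predm,
    predicted_predm = pred_predm,
    ratio_predm = ifelse(obs_predm > 0, pred_predm / obs_predm, NA_real_),
    observed_dm = obs_dm,
    predicted_dm = pred_dm,
    ratio_dm = ifelse(obs_dm > 0, pred_dm / obs_dm, NA_real_)
  )

  structure(list(
    table = tab,
    half_sizes = c(a = length(idx$a), b = length(idx$b)),
    coef_max_abs_diff = max(dmat),
    coef_mean_abs_diff = mean(dmat),
    fit_a = fit_a
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Split-sample validation (halves of %d and %d records)\n",
              x$half_sizes["a"], x$half_sizes["b"]))
  cat(sprintf("  max |slope difference| between half-fits: %.3f\n",
              x$coef_max_abs_diff))
  print(x$table)
  invisible(x)
}
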