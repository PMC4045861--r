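# Risk profiles: combining the polytomous fit with the diagnosed-prediabetes
# equation, prediction, odds ratios and standardized effects.

coef_matrix_from <- function(polytomous) {
  if (inherits(polytomous, "polytomous_fit")) return(polytomous$coef)
  if (is.matrix(polytomous) && ncol(polytomous) == 2) return(polytomous)
  schema_error("'polytomous' must be a polytomous_fit or a coefficient matrix with 2 columns")
}

coef_vector_from <- function(diag_predm) {
  if (inherits(diag_predm, "binary_fit")) return(diag_predm$coef)
  if (is.numeric(diag_predm)) return(diag_predm)
  schema_error("'diag_predm' must be a binary_fit or a named numeric vector")
}

#' Bundle fitted coefficients into a risk model
#'
#' A risk model pairs the polytomous coefficients (prediabetes and
#' undiagnosed diabetes versus normal) with the diagnosed-prediabetes
#' binary-logistic coefficients, which together determine every person's
#' risk profile.
#'
#' @param polytomous A [fit_polytomous()] result or a coefficient matrix
#'   (rows: intercept + design terms; columns: prediabetes, undiag_dm).
#' @param diag_predm A [fit_binary()] result or named coefficient vector for
#'   the diagnosed-prediabetes equation.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(polytomous, diag_predm) {
  B <- coef_matrix_from(polytomous)
  d <- coef_vector_from(diag_predm)
  if (!identical(rownames(B), names(d))) {
    schema_error("polytomous and diagnosed-prediabetes coefficients use different design layouts")
  }
  structure(list(polytomous = B, diag_predm = d,
                 fits = list(
                   polytomous = if (inherits(polytomous, "polytomous_fit")) polytomous,
                   diag_predm = if (inherits(diag_predm, "binary_fit")) diag_predm)),
            class = "risk_model")
}

#' Predict per-person risk profiles
#'
#' Evaluates the polytomous model by softmax over (normal, total
#' prediabetes, undiagnosed diabetes), the diagnosed-prediabetes probability
#' by the logistic function, and derives the undetected-prediabetes
#' probability as the total-prediabetes probability minus the
#' diagnosed-prediabetes probability, clamped below at zero (the subtraction
#' can go negative for low-risk covariate patterns).
#'
#' @param records Person table with the design covariates.
#' @param model A [risk_model()].
#' @return Tibble with columns `p_normal`, `p_total_predm`, `p_undiag_dm`,
#'   `p_diag_predm`, `p_undet_predm`; the first three sum to 1 row-wise.
#' @export
predict_risk <- function(records, model) {
  if (!inherits(model, "risk_model")) {
    schema_error("'model' must be a risk_model object")
  }
  X <- build_design_matrix(records)
  if (!identical(colnames(X), rownames(model$polytomous))) {
    # allow models fitted on a term subset
    if (!all(rownames(model$polytomous) %in% colnames(X))) {
      schema_error("record covariates do not conform to the model's design layout")
    }
    X <- X[, rownames(model$polytomous), drop = FALSE]
  }
  P <- softmax3(drop(X %*% model$polytomous[, 1]),
                drop(X %*% model$polytomous[, 2]))
  p_diag <- stats::plogis(drop(X %*% model$diag_predm))
  tibble::tibble(
    p_normal = P[, 1],
    p_total_predm = P[, 2],
    p_undiag_dm = P[, 3],
    p_diag_predm = p_diag,
    p_undet_predm = pmax(0, P[, 2] - p_diag)
  )
}

#' Odds ratios from a fitted model
#'
#' Elementwise exponential of the slope coefficients (intercepts excluded).
#'
#' @param fit A [fit_polytomous()] or [fit_binary()] result.
#' @return Tibble with columns `term`, `outcome`, `odds_ratio`.
#' @export
odds_ratios <- function(fit) {
  if (inherits(fit, "polytomous_fit")) {
    B <- fit$coef[rownames(fit$coef) != "(Intercept)", , drop = FALSE]
    tibble::tibble(
      term = rep(rownames(B), times = ncol(B)),
      outcome = rep(colnames(B), each = nrow(B)),
      odds_ratio = as.vector(exp(B))
    )
  } else if (inherits(fit, "binary_fit")) {
    b <- fit$coef[names(fit$coef) != "(Intercept)"]
    tibble::tibble(term = names(b), outcome = "outcome",
                   odds_ratio = unname(exp(b)))
  } else {
    schema_error("'fit' must be a polytomous_fit or binary_fit")
  }
}

#' Standardized effect of one characteristic on an outcome probability
#'
#' Evaluates the predicted outcome probability at the population-average
#' design vector with the characteristic of interest switched on versus off
#' (for a level of a categorical block, the level's indicator is set to 1
#' with its sibling indicators 0, versus the whole block at the reference
#' level), and returns the difference in percentage points.
#'
#' @param model A [risk_model()] or [fit_polytomous()] result.
#' @param characteristic A binary design term or categorical level name from
#'   [design_terms()] (e.g. `"obese"`, `"male"`, `"age_45_54"`). The
#'   continuous income term is not supported.
#' @param population Person table whose weighted covariate means define the
#'   reference profile.
#' @param outcome `"undiag_dm"` or `"total_predm"`.
#' @param weight_col Weight column in `population`.
#' @return Percentage-point difference (numeric scalar).
#' @export
standardized_effect <- function(model, characteristic, population,
                                outcome = c("undiag_dm", "total_predm"),
                                weight_col = "weight") {
  outcome <- match.arg(outcome)
  B <- if (inherits(model, "risk_model")) model$polytomous else
    coef_matrix_from(model)
  terms <- setdiff(rownames(B), "(Intercept)")
  if (!characteristic %in% terms || characteristic == "income_k") {
    schema_error(sprintf(
      "'%s' is not a switchable design characteristic", characteristic))
  }
  X <- build_design_matrix(population)[, rownames(B), drop = FALSE]
  w <- as.numeric(population[[weight_col]])
  xbar <- drop(crossprod(X, w)) / sum(w)

  blocks <- design_blocks()
  in_block <- vapply(blocks, function(b) characteristic %in% b, logical(1))
  siblings <- if (any(in_block)) blocks[[which(in_block)[1]]] else characteristic

  x_on <- x_off <- xbar
  x_on[intersect(siblings, names(x_on))] <- 0
  x_off[intersect(siblings, names(x_off))] <- 0
  x_on[characteristic] <- 1

  prob_at <- function(x) {
    P <- softmax3(sum(x * B[, 1]), sum(x * B[, 2]))
    if (outcome == "undiag_dm") P[, 3] else P[, 2]
  }
  100 * (prob_at(x_on) - prob_at(x_off))
}
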