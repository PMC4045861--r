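# Survey-weighted logistic and polytomous (multinomial) logistic fitting by
# Newton-Raphson on the weight-multiplied log-likelihood (pseudo-MLE:
# weights enter as frequency-style multipliers of each record's likelihood
# contribution).
#
# Numerical contract: convergence when the largest absolute element of the
# score vector falls below `tol` (weights are normalised to mean 1 for
# fitting, which makes both the criterion and the estimates invariant to
# rescaling all weights by a positive constant); at most `max_iter` full
# Newton steps with step-halving if a step decreases the log-likelihood; a
# small ridge (1e-6) is added to the Hessian diagonal if it is singular.
# Reported standard errors are model-based (inverse observed information at
# the optimum, mean-1 weights); they ignore the design effect of unequal
# weights and are labelled accordingly.

multinomial_loglik <- function(B, X, y_idx, w) {
  K1 <- ncol(B)
  eta <- X %*% B
  m <- pmax(0, apply(eta, 1, max))
  den <- exp(-m) + rowSums(exp(eta - m))
  lin <- ifelse(y_idx == 1, 0, eta[cbind(seq_along(y_idx),
                                         pmax(y_idx - 1, 1))])
  sum(w * (lin - m - log(den)))
}

fit_weighted_multinomial <- function(X, y_idx, w, K, tol = 1e-8,
                                     max_iter = 100, ridge = 1e-6) {
  n <- nrow(X)
  p <- ncol(X)
  K1 <- K - 1
  B <- matrix(0, p, K1)
  ll <- multinomial_loglik(B, X, y_idx, w)
  converged <- FALSE
  iter <- 0

  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(0, apply(eta, 1, max))
    E <- cbind(exp(-m), exp(eta - m))
    E / rowSums(E)
  }

  repeat {
    P <- probs(B)
    G <- vapply(seq_len(K1), function(k) {
      drop(crossprod(X, w * ((y_idx == k + 1) - P[, k + 1])))
    }, numeric(p))
    g <- as.vector(G)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1

    H <- matrix(0, p * K1, p * K1)
    for (k in seq_len(K1)) {
      for (l in k:K1) {
        wkl <- w * P[, k + 1] * ((k == l) - P[, l + 1])
        blk <- crossprod(X, X * wkl)
        rk <- (k - 1) * p + seq_len(p)
        rl <- (l - 1) * p + seq_len(p)
        H[rk, rl] <- blk
        if (l != k) H[rl, rk] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(ridge, nrow(H)), g)
    })
    # step-halving to guarantee ascent
    lambda <- 1
    repeat {
      B_try <- B + lambda * matrix(step, p, K1)
      ll_try <- multinomial_loglik(B_try, X, y_idx, w)
      if (is.finite(ll_try) && ll_try >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    B <- B + lambda * matrix(step, p, K1)
    ll <- multinomial_loglik(B, X, y_idx, w)
  }

  # observed information at the optimum, for model-based SEs
  P <- probs(B)
  H <- matrix(0, p * K1, p * K1)
  for (k in seq_len(K1)) {
    for (l in k:K1) {
      wkl <- w * P[, k + 1] * ((k == l) - P[, l + 1])
      blk <- crossprod(X, X * wkl)
      rk <- (k - 1) * p + seq_len(p)
      rl <- (l - 1) * p + seq_len(p)
      H[rk, rl] <- blk
      if (l != k) H[rl, rk] <- t(blk)
    }
  }
  vcov <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(ridge, nrow(H)))
  })
  se <- matrix(sqrt(pmax(diag(vcov), 0)), p, K1)
  dimnames(B) <- dimnames(se) <- list(colnames(X), NULL)

  list(coef = B, se = se, vcov = vcov, loglik = ll,
       converged = converged, n_iter = iter, max_score = max(abs(g)))
}

select_design <- function(records, terms) {
  X <- build_design_matrix(records)
  if (is.null(terms)) return(X)
  bad <- setdiff(terms, design_terms())
  if (length(bad)) {
    schema_error(paste0("unknown design term(s): ", paste(bad, collapse = ", ")))
  }
  X[, c("(Intercept)", terms), drop = FALSE]
}

#' Fit the survey-weighted polytomous risk model
#'
#' Fits the three-category (normal / prediabetes / undiagnosed diabetes)
#' multinomial logistic model with the normal category as reference,
#' maximising the weight-multiplied log-likelihood by Newton-Raphson.
#'
#' @param records Person table containing the design covariates and a weight
#'   column. Diagnosed-diabetes records must already be excluded.
#' @param status Outcome: either the name of a column in `records` or a
#'   vector. Five-level statuses are collapsed with [collapse_status()].
#' @param weight_col Name of the sampling-weight column.
#' @param terms Optional subset of [design_terms()] to use as covariates
#'   (default: all).
#' @param tol Convergence tolerance on the largest absolute score element
#'   (mean-1 weights).
#' @param max_iter Maximum number of Newton steps.
#' @return An object of class `polytomous_fit` with elements `coef` (27 x 2
#'   matrix, columns `prediabetes` and `undiag_dm`), `se`, `vcov`,
#'   `loglik` (on the original weight scale), `converged`, `n_iter`, `n`.
#' @export
fit_polytomous <- function(records, status = "status", weight_col = "weight",
                           terms = NULL, tol = 1e-8, max_iter = 100) {
  y_raw <- if (is.character(status) && length(status) == 1) {
    if (!status %in% names(records)) {
      schema_error(sprintf("status column '%s' not found", status))
    }
    records[[status]]
  } else {
    status
  }
  y <- if (is.factor(y_raw) &&
           identical(levels(y_raw), c("normal", "prediabetes", "undiag_dm"))) {
    y_raw
  } else {
    collapse_status(y_raw)
  }
  if (anyNA(y)) missing_data_error("status contains missing values")
  counts <- table(y)
  if (any(counts == 0)) {
    degenerate_data_error(paste0("empty outcome category: ",
                                 paste(names(counts)[counts == 0],
                                       collapse = ", ")))
  }
  w <- as.numeric(records[[weight_col]])
  if (anyNA(w) || any(w <= 0)) {
    schema_error("weights must be strictly positive")
  }
  X <- select_design(records, terms)
  w_fit <- w / mean(w)
  fit <- fit_weighted_multinomial(X, as.integer(y), w_fit, K = 3,
                                  tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    sy_stop(sprintf(
      "polytomous fit did not converge in %d iterations (max |score| = %g)",
      max_iter, fit$max_score),
      class = "sy_nonconvergence_error", last_coef = fit$coef)
  }
  colnames(fit$coef) <- colnames(fit$se) <- c("prediabetes", "undiag_dm")
  structure(
    list(coef = fit$coef, se = fit$se, vcov = fit$vcov,
         loglik = fit$loglik * mean(w), converged = fit$converged,
         n_iter = fit$n_iter, n = nrow(X),
         outcome_levels = c("normal", "prediabetes", "undiag_dm"),
         terms = colnames(X)),
    class = "polytomous_fit")
}

#' Fit a survey-weighted binary logistic model
#'
#' Used for the auxiliary diagnosed-prediabetes (and optionally
#' diagnosed-diabetes) equations. Same weighting, convergence and error
#' contract as [fit_polytomous()].
#'
#' @param records Person table with design covariates and weights.
#' @param outcome Column name or 0/1 vector.
#' @inheritParams fit_polytomous
#' @return An object of class `binary_fit` with `coef` (named vector), `se`,
#'   `vcov`, `loglik`, `converged`, `n_iter`, `n`.
#' @export
fit_binary <- function(records, outcome, weight_col = "weight", terms = NULL,
                       tol = 1e-8, max_iter = 100) {
  y <- if (is.character(outcome) && length(outcome) == 1) {
    if (!outcome %in% names(records)) {
      schema_error(sprintf("outcome column '%s' not found", outcome))
    }
    records[[outcome]]
  } else {
    outcome
  }
  y <- as.numeric(y)
  if (anyNA(y) || any(y != 0 & y != 1)) {
    missing_data_error("binary outcome must be 0/1 for all records")
  }
  if (all(y == 0) || all(y == 1)) {
    degenerate_data_error("binary outcome has a single observed class")
  }
  w <- as.numeric(records[[weight_col]])
  if (anyNA(w) || any(w <= 0)) {
    schema_error("weights must be strictly positive")
  }
  X <- select_design(records, terms)
  w_fit <- w / mean(w)
  fit <- fit_weighted_multinomial(X, as.integer(y) + 1L, w_fit, K = 2,
                                  tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    sy_stop(sprintf(
      "binary fit did not converge in %d iterations (max |score| = %g)",
      max_iter, fit$max_score),
      class = "sy_nonconvergence_error", last_coef = fit$coef)
  }
  structure(
    list(coef = setNames(drop(fit$coef), colnames(X)),
         se = setNames(drop(fit$se), colnames(X)),
         vcov = fit$vcov, loglik = fit$loglik * mean(w),
         converged = fit$converged, n_iter = fit$n_iter, n = nrow(X),
         terms = colnames(X)),
    class = "binary_fit")
}
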