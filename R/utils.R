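# Structured conditions ------------------------------------------------------

sy_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "screenyield_error")))
}

config_error <- function(field, msg) {
  sy_stop(sprintf("invalid scenario configuration: field '%s' %s", field, msg),
          class = "sy_config_error", field = field)
}

missing_data_error <- function(msg) {
  sy_stop(msg, class = "sy_missing_data_error")
}

degenerate_data_error <- function(msg, ...) {
  sy_stop(msg, class = "sy_degenerate_data_error", ...)
}

schema_error <- function(msg) {
  sy_stop(msg, class = "sy_schema_error")
}

# Numeric helpers -------------------------------------------------------------

#' Round half away from zero
#'
#' Presentation-layer rounding used for published-style tables: exact halves
#' round away from zero (so 2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(18.6)       # 19
#' round_half_up(2.2375, 1)  # 2.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Weighted quantile of type "inverse empirical CDF" (left-continuous).
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}
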