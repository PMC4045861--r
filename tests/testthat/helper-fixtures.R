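# Shared fixture builders for the test suite.

# A single person record with every covariate at its reference/default value;
# override any column by name.
make_records <- function(n = 1, ...) {
  base <- tibble::tibble(
    id = seq_len(n),
    weight = rep(1, n),
    male = 0, age_band = "18-34", race_eth = "nh_white",
    asthma = 0, arthritis = 0, heart_attack = 0, stroke = 0, cancer = 0,
    hypertension = 0, high_cholesterol = 0, cvd = 0, smoker = 0,
    bmi_class = "normal", income_k = 40, insured = 1, medicaid = 0,
    survey_wave = "2003-04", pregnant = 0,
    diagnosed_diabetes = 0, diagnosed_prediabetes = 0
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Random covariate table for property-style tests.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    cov <- screenyield:::draw_covariates(n, default_covariate_spec())
    tibble::tibble(id = seq_len(n),
                   weight = stats::rlnorm(n, log(1000), 0.5),
                   cov,
                   diagnosed_diabetes = 0, diagnosed_prediabetes = 0)
  })
}

# Random risk profiles aligned with a record table.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    p_dm <- stats::runif(n, 0, 0.3)
    p_pre <- stats::runif(n, 0, 0.6)
    p_diag <- stats::runif(n, 0, 0.1)
    tibble::tibble(
      p_normal = pmax(0, 1 - p_pre - p_dm),
      p_total_predm = p_pre,
      p_undiag_dm = p_dm,
      p_diag_predm = p_diag,
      p_undet_predm = pmax(0, p_pre - p_diag)
    )
  })
}

# Brute-force O(n^2) concordance oracle: explicit enumeration of all
# positive-negative pairs.
concordance_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  d <- outer(pos, neg, `-`)
  n_conc <- sum(d > 0)
  n_disc <- sum(d < 0)
  n_tied <- sum(d == 0)
  P <- length(pos) * length(neg)
  list(pct_concordant = 100 * n_conc / P, pct_discordant = 100 * n_disc / P,
       pct_tied = 100 * n_tied / P, n_pairs = P,
       somers_d = (n_conc - n_disc) / P, c_statistic = (n_conc + n_tied / 2) / P)
}
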