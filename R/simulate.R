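# Synthetic survey generators.
#
# Two surveys share one covariate model and one latent glycemic-state model:
# the "model survey" (NHANES-like) carries lab panels and diagnosis flags,
# the "projection survey" (MEPS-like) carries annual visit counts instead of
# labs. Generation is fully vectorised from a single seeded RNG stream, so a
# given (config, seed) pair is bit-reproducible.

.glycemic_states <- c("normal", "prediabetes", "diabetes")

# Uniform sampling ranges per (test, latent category). Category membership is
# what matters downstream, so values are drawn uniformly over each category's
# defining interval; diabetes ranges are capped at clinically plausible
# maxima (HbA1c 14%, FPG 300 mg/dL, 2-h OGTT 400 mg/dL).
.lab_ranges <- list(
  hba1c = list(normal = c(4.5, 5.7), prediabetes = c(5.7, 6.4),
               diabetes = c(6.5, 14)),
  fpg   = list(normal = c(75, 100), prediabetes = c(100, 125),
               diabetes = c(126, 300)),
  ogtt  = list(normal = c(80, 140), prediabetes = c(140, 199),
               diabetes = c(200, 400))
)

softmax3 <- function(eta1, eta2) {
  # category order: reference (0), eta1, eta2
  m <- pmax(0, eta1, eta2)
  e0 <- exp(-m)
  e1 <- exp(eta1 - m)
  e2 <- exp(eta2 - m)
  den <- e0 + e1 + e2
  cbind(e0 / den, e1 / den, e2 / den)
}

draw_covariates <- function(n, cs) {
  male <- stats::rbinom(n, 1, cs$p_male)
  age  <- sample(.age_levels, n, replace = TRUE, prob = cs$age_probs)
  race <- sample(.race_levels, n, replace = TRUE, prob = cs$race_probs)
  a_idx <- match(age, .age_levels)

  # BMI class: baseline mixture tilted toward overweight/obese with age
  s <- cs$bmi_age_shift
  w_norm <- rep(cs$bmi_base_probs[["normal"]], n)
  w_over <- cs$bmi_base_probs[["overweight"]] * exp(0.5 * s * (a_idx - 1))
  w_ob   <- cs$bmi_base_probs[["obese"]] * exp(s * (a_idx - 1))
  tot <- w_norm + w_over + w_ob
  u <- stats::runif(n)
  bmi <- ifelse(u < w_norm / tot, "normal",
                ifelse(u < (w_norm + w_over) / tot, "overweight", "obese"))
  b_idx <- match(bmi, .bmi_levels)

  conditions <- lapply(.condition_vars, function(v) {
    p <- stats::plogis(stats::qlogis(cs$condition_base[[v]]) +
                         cs$condition_age_slope[[v]] * (a_idx - 1) +
                         cs$condition_bmi_slope[[v]] * (b_idx - 1))
    stats::rbinom(n, 1, p)
  })
  names(conditions) <- .condition_vars

  smoker <- stats::rbinom(n, 1, cs$smoking_rate)
  income_k <- stats::rlnorm(n, cs$income_meanlog, cs$income_sdlog)
  insured <- stats::rbinom(n, 1, cs$insured_rate)
  medicaid <- stats::rbinom(n, 1, cs$medicaid_rate)
  insured <- pmax(insured, medicaid)  # Medicaid coverage implies insurance
  wave <- sample(.wave_levels, n, replace = TRUE, prob = cs$wave_probs)
  pregnant <- as.integer(male == 0 & stats::runif(n) < cs$pregnancy_rate)

  tibble::tibble(
    male = male, age_band = age, race_eth = race,
    !!!conditions,
    smoker = smoker, bmi_class = bmi, income_k = income_k,
    insured = insured, medicaid = medicaid, survey_wave = wave,
    pregnant = pregnant
  )
}

draw_latent_state <- function(X, tm) {
  P <- softmax3(drop(X %*% tm$prediabetes), drop(X %*% tm$diabetes))
  u <- stats::runif(nrow(X))
  .glycemic_states[1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])]
}

draw_lab_values <- function(state, config) {
  n <- length(state)
  assigned <- cbind(
    hba1c = stats::runif(n) < config$lab_assignment[["hba1c"]],
    fpg   = stats::runif(n) < config$lab_assignment[["fpg"]],
    ogtt  = stats::runif(n) < config$lab_assignment[["ogtt"]]
  )
  none <- !assigned[, "hba1c"] & !assigned[, "fpg"] & !assigned[, "ogtt"]
  assigned[none, "hba1c"] <- TRUE  # every record must be classifiable

  draw_one <- function(test) {
    cat <- state
    if (config$discordance_rate > 0) {
      flip <- stats::runif(n) < config$discordance_rate
      other <- vapply(cat, function(cc) {
        sample(setdiff(.glycemic_states, cc), 1)
      }, character(1))
      cat[flip] <- other[flip]
    }
    val <- rep(NA_real_, n)
    for (cc in .glycemic_states) {
      idx <- assigned[, test] & cat == cc
      rng <- .lab_ranges[[test]][[cc]]
      val[idx] <- stats::runif(sum(idx), rng[1], rng[2])
    }
    val
  }
  list(hba1c = draw_one("hba1c"), fpg = draw_one("fpg"),
       ogtt_2h = draw_one("ogtt"))
}

#' Generate a model (lab-bearing) survey population
#'
#' Draws a synthetic survey of the kind used to *fit* the risk model: each
#' record carries the design covariates, a positive sampling weight, a
#' pregnancy flag, diagnosis flags, a partial lab panel (HbA1c / FPG /
#' 2-h OGTT) drawn consistently with the record's latent glycemic state, and
#' the latent state itself (kept for recovery tests; real surveys do not have
#' it). The latent state is drawn from the configured polytomous model
#' evaluated at the record's covariates; diagnosis flags are drawn from the
#' configured binary-logistic models conditional on the latent state.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per person.
#' @export
#' @examples
#' sv <- generate_model_survey(scenario_config(population_size = 500, seed = 7))
#' table(sv$latent_state)
generate_model_survey <- function(config) {
  if (!inherits(config, "scenario_config")) {
    config_error("config", "must be a scenario_config object")
  }
  with_preserved_rng(config$seed, {
    n <- config$population_size
    cov <- draw_covariates(n, config$covariate_spec)
    X <- build_design_matrix(cov)
    tm <- config$true_model
    state <- draw_latent_state(X, tm)
    labs <- draw_lab_values(state, config)

    p_diag_predm <- stats::plogis(drop(X %*% tm$diagnosed_predm))
    p_diag_dm <- stats::plogis(drop(X %*% tm$diagnosed_dm))
    diagnosed_prediabetes <- as.integer(
      state == "prediabetes" & stats::runif(n) < p_diag_predm)
    diagnosed_diabetes <- as.integer(
      state == "diabetes" & stats::runif(n) < p_diag_dm)

    weight <- stats::rlnorm(n, config$weight_spec$meanlog,
                            config$weight_spec$sdlog)

    tibble::tibble(id = seq_len(n), weight = weight, cov,
                   diagnosed_diabetes = diagnosed_diabetes,
                   diagnosed_prediabetes = diagnosed_prediabetes,
                   hba1c = labs$hba1c, fpg = labs$fpg, ogtt_2h = labs$ogtt_2h,
                   latent_state = state)
  })
}

#' Generate a projection (utilisation-bearing) survey population
#'
#' Draws a synthetic survey of the kind the fitted risk model is *projected
#' onto*: the same covariates, weights, pregnancy and diagnosed-diabetes
#' flags as the model survey, but annual health-care visit counts in five
#' settings instead of a lab panel. Visit counts are negative binomial with
#' means linear in the record's true probability of undiagnosed diabetes, so
#' utilisation rises with latent risk as observed in US expenditure-survey
#' data.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per person.
#' @export
generate_projection_survey <- function(config) {
  if (!inherits(config, "scenario_config")) {
    config_error("config", "must be a scenario_config object")
  }
  with_preserved_rng(config$seed, {
    n <- config$population_size
    cov <- draw_covariates(n, config$covariate_spec)
    X <- build_design_matrix(cov)
    tm <- config$true_model
    state <- draw_latent_state(X, tm)
    diagnosed_diabetes <- as.integer(
      state == "diabetes" &
        stats::runif(n) < stats::plogis(drop(X %*% tm$diagnosed_dm)))

    # true probability of *undiagnosed* diabetes drives utilisation
    P <- softmax3(drop(X %*% tm$prediabetes), drop(X %*% tm$diabetes))
    p_udm_true <- P[, 3] * (1 - stats::plogis(drop(X %*% tm$diagnosed_dm)))

    vs <- config$visit_spec
    visits <- lapply(.visit_vars, function(v) {
      mu <- vs$base[[v]] + vs$risk_slope[[v]] * p_udm_true
      cnt <- if (is.infinite(vs$dispersion)) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, size = vs$dispersion, mu = mu)
      }
      if (vs$zero_inflation > 0) {
        cnt[stats::runif(n) < vs$zero_inflation] <- 0L
      }
      cnt
    })
    names(visits) <- .visit_vars

    weight <- stats::rlnorm(n, config$weight_spec$meanlog,
                            config$weight_spec$sdlog)

    tibble::tibble(id = seq_len(n), weight = weight, cov,
                   diagnosed_diabetes = diagnosed_diabetes,
                   !!!visits,
                   latent_state = state)
  })
}
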