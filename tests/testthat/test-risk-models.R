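# Independently coded weighted multinomial log-likelihood used as the
# optimizer cross-check oracle (deliberately written differently from the
# package's internal likelihood).
oracle_negll <- function(par, X, y, w) {
  p <- ncol(X)
  b1 <- par[1:p]
  b2 <- par[(p + 1):(2 * p)]
  e1 <- exp(X %*% b1)
  e2 <- exp(X %*% b2)
  den <- 1 + e1 + e2
  ll <- sum(w * (log(ifelse(y == "normal", 1,
                            ifelse(y == "prediabetes", e1, e2))) - log(den)))
  -ll
}

test_that("risk profiles follow the closed-form softmax and clamp rules", {
  rec <- make_records(1)
  zero <- setNames(rep(0, 27), c("(Intercept)", design_terms()))
  m0 <- risk_model(cbind(prediabetes = zero, undiag_dm = zero), zero)
  pr <- predict_risk(rec, m0)
  expect_equal(pr$p_normal, 1 / 3, tolerance = 1e-12)
  expect_equal(pr$p_total_predm, 1 / 3, tolerance = 1e-12)
  expect_equal(pr$p_undiag_dm, 1 / 3, tolerance = 1e-12)
  expect_equal(pr$p_diag_predm, 1 / 2, tolerance = 1e-12)
  expect_equal(pr$p_undet_predm, 0)  # clamped at zero

  # hand-set coefficients against direct formula evaluation
  b1 <- zero; b1["(Intercept)"] <- -1.2; b1["male"] <- 0.4; b1["obese"] <- 0.7
  b2 <- zero; b2["(Intercept)"] <- -2.5; b2["income_k"] <- -0.002
  d  <- zero; d["(Intercept)"] <- -2.0; d["hypertension"] <- 0.6
  rec2 <- make_records(1, male = 1, bmi_class = "obese", hypertension = 1,
                       income_k = 55)
  m <- risk_model(cbind(prediabetes = b1, undiag_dm = b2), d)
  pr2 <- predict_risk(rec2, m)
  e1 <- exp(-1.2 + 0.4 + 0.7)
  e2 <- exp(-2.5 - 0.002 * 55)
  expect_equal(pr2$p_total_predm, e1 / (1 + e1 + e2), tolerance = 1e-12)
  expect_equal(pr2$p_undiag_dm, e2 / (1 + e1 + e2), tolerance = 1e-12)
  pd <- 1 / (1 + exp(2.0 - 0.6))
  expect_equal(pr2$p_diag_predm, pd, tolerance = 1e-12)
  expect_equal(pr2$p_undet_predm, max(0, e1 / (1 + e1 + e2) - pd),
               tolerance = 1e-12)
})

test_that("risk profiles always normalise and respect the clamp bounds", {
  withr::with_seed(7, {
    for (i in 1:20) {
      nms <- c("(Intercept)", design_terms())
      B <- cbind(prediabetes = setNames(rnorm(27, 0, 0.5), nms),
                 undiag_dm = setNames(rnorm(27, 0, 0.5), nms))
      d <- setNames(rnorm(27, 0, 0.5), nms)
      rec <- random_records(50, seed = i)
      pr <- predict_risk(rec, risk_model(B, d))
      expect_equal(pr$p_normal + pr$p_total_predm + pr$p_undiag_dm,
                   rep(1, 50), tolerance = 1e-9)
      expect_true(all(pr$p_undet_predm >= 0 &
                        pr$p_undet_predm <= pr$p_total_predm + 1e-12))
    }
  })
})

test_that("balanced intercept-only binary fit returns a zero intercept", {
  rec <- make_records(200)
  y <- rep(c(0, 1), 100)
  fit <- fit_binary(rec, y, terms = character(0))
  expect_lt(abs(fit$coef[["(Intercept)"]]), 1e-6)
  expect_true(fit$converged)
})

test_that("single-class binary outcomes raise a degenerate-data error", {
  rec <- make_records(50)
  expect_error(fit_binary(rec, rep(0, 50), terms = character(0)),
               class = "sy_degenerate_data_error")
  expect_error(fit_binary(rec, rep(1, 50), terms = character(0)),
               class = "sy_degenerate_data_error")
})

test_that("polytomous fitter agrees with a generic optimizer on the same likelihood", {
  withr::with_seed(42, {
    n <- 200
    rec <- make_records(n, male = rbinom(n, 1, 0.5),
                        income_k = round(runif(n, 10, 100), 1),
                        weight = rlnorm(n, 0, 0.4))
    eta1 <- -0.3 + 0.8 * rec$male - 0.01 * rec$income_k
    eta2 <- -1.0 + 0.5 * rec$male
    u <- runif(n)
    p1 <- exp(eta1) / (1 + exp(eta1) + exp(eta2))
    p2 <- exp(eta2) / (1 + exp(eta1) + exp(eta2))
    rec$status <- factor(ifelse(u < p1, "prediabetes",
                                ifelse(u < p1 + p2, "undiag_dm", "normal")),
                         levels = c("normal", "prediabetes", "undiag_dm"))
  })
  fit <- fit_polytomous(rec, terms = c("male", "income_k"))
  X <- cbind(1, rec$male, rec$income_k)
  w <- rec$weight / mean(rec$weight)
  opt <- optim(rep(0, 6), oracle_negll, X = X, y = as.character(rec$status),
               w = w, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 5000,
                              parscale = rep(c(1, 1, 0.02), 2)))
  expect_lt(max(abs(c(fit$coef) - opt$par)), 1e-5)

  # second independent cross-check: nnet::multinom on the same data
  skip_if_not_installed("nnet")
  mn <- nnet::multinom(status ~ male + income_k, data = rec,
                       weights = w, trace = FALSE, reltol = 1e-14)
  expect_lt(max(abs(c(t(coef(mn))) - c(fit$coef))), 1e-3)
})

test_that("null-model fits recover category log-odds and zero slopes", {
  withr::with_seed(3, {
    n <- 6000
    rec <- make_records(n, male = rbinom(n, 1, 0.5))
    rec$status <- factor(sample(c("normal", "prediabetes", "undiag_dm"), n,
                                replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                         levels = c("normal", "prediabetes", "undiag_dm"))
  })
  fit <- fit_polytomous(rec, terms = "male")
  counts <- table(rec$status)
  expect_equal(fit$coef["(Intercept)", "prediabetes"],
               log(counts[["prediabetes"]] / counts[["normal"]]),
               tolerance = 0.1)
  expect_lt(abs(fit$coef["male", "prediabetes"]),
            3 * fit$se["male", "prediabetes"])
  expect_lt(abs(fit$coef["male", "undiag_dm"]),
            3 * fit$se["male", "undiag_dm"])
})

test_that("fits are invariant to rescaling all weights by a positive constant", {
  sv <- generate_model_survey(scenario_config(population_size = 4000, seed = 17))
  kept <- apply_exclusions(sv)$kept
  kept$status <- assign_status(kept)
  f1 <- fit_polytomous(kept)
  kept2 <- kept
  kept2$weight <- kept2$weight * 737.5
  f2 <- fit_polytomous(kept2)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  b1 <- fit_binary(kept, "diagnosed_prediabetes")
  b2 <- fit_binary(kept2, "diagnosed_prediabetes")
  expect_equal(b1$coef, b2$coef, tolerance = 1e-12)
})

test_that("empty outcome categories raise a degenerate-data error", {
  rec <- make_records(100)
  rec$status <- factor(rep(c("normal", "prediabetes"), 50),
                       levels = c("normal", "prediabetes", "undiag_dm"))
  expect_error(fit_polytomous(rec, terms = "male"),
               class = "sy_degenerate_data_error")
})

test_that("slope bias of the polytomous fitter decreases with sample size", {
  truth <- default_true_coefficients()
  slope_names <- design_terms()
  bias_at <- function(n, seed) {
    cfg <- scenario_config(population_size = n, seed = seed)
    sv <- generate_model_survey(cfg)
    kept <- apply_exclusions(sv)$kept
    kept$status <- assign_status(kept)
    fit <- fit_polytomous(kept)
    est <- c(fit$coef[slope_names, "prediabetes"],
             fit$coef[slope_names, "undiag_dm"])
    tru <- c(truth$prediabetes[slope_names], truth$diabetes[slope_names])
    mean(abs(est - tru))
  }
  b <- c(bias_at(5000, 101), bias_at(20000, 101), bias_at(80000, 101))
  expect_true(all(diff(b) < 0))
})

test_that("odds ratios are elementwise exponentials of the slopes", {
  sv <- generate_model_survey(scenario_config(population_size = 5000, seed = 55))
  kept <- apply_exclusions(sv)$kept
  kept$status <- assign_status(kept)
  fit <- fit_polytomous(kept)
  or <- odds_ratios(fit)
  expect_equal(nrow(or), 2 * length(design_terms()))
  expect_false("(Intercept)" %in% or$term)
  i <- which(or$term == "obese" & or$outcome == "prediabetes")
  expect_equal(or$odds_ratio[i], exp(fit$coef["obese", "prediabetes"]))
})

test_that("standardized effects match manual softmax arithmetic", {
  nms <- c("(Intercept)", design_terms())
  b1 <- setNames(rep(0, 27), nms); b1["(Intercept)"] <- -1; b1["obese"] <- 0.9
  b2 <- setNames(rep(0, 27), nms); b2["(Intercept)"] <- -2; b2["obese"] <- 1.1
  d <- setNames(rep(0, 27), nms)
  m <- risk_model(cbind(prediabetes = b1, undiag_dm = b2), d)
  pop <- random_records(500, seed = 9)

  # zero-slope characteristic has zero effect
  expect_equal(standardized_effect(m, "smoker", pop, "undiag_dm"), 0)

  # manual evaluation at the weighted population mean with the BMI block
  # switched between obese and the (normal-weight) reference
  X <- build_design_matrix(pop)
  xbar <- drop(crossprod(X, pop$weight)) / sum(pop$weight)
  x_on <- x_off <- xbar
  x_on[c("overweight", "obese")] <- c(0, 1)
  x_off[c("overweight", "obese")] <- 0
  pr <- function(x) {
    e1 <- exp(sum(x * b1)); e2 <- exp(sum(x * b2))
    e2 / (1 + e1 + e2)
  }
  expect_equal(standardized_effect(m, "obese", pop, "undiag_dm"),
               100 * (pr(x_on) - pr(x_off)), tolerance = 1e-10)
  expect_error(standardized_effect(m, "not_a_term", pop),
               class = "sy_schema_error")
})

test_that("obesity raises undiagnosed-diabetes risk by single-digit percentage points", {
  truth <- default_true_coefficients()
  m <- risk_model(cbind(prediabetes = truth$prediabetes,
                        undiag_dm = truth$diabetes),
                  truth$diagnosed_predm)
  pop <- random_records(4000, seed = 314)
  pop <- pop[pop$age_band == "45-54", ]
  eff <- standardized_effect(m, "obese", pop, "undiag_dm")
  expect_gt(eff, 0)
  expect_lt(eff, 10)
})

test_that("calibration scale factor reproduces target totals", {
  expect_equal(round_half_up(calibrate_scale(88.2, 86.0), 3), 0.975)
  expect_equal(calibrate_scale(c(7, 80), c(7, 80)), 1.0)
  s <- calibrate_scale(c(7.4, 81.1), c(7, 79))
  expect_equal(sum(c(7.4, 81.1) * s), 86, tolerance = 1e-9)
  expect_error(calibrate_scale(c(0, 0), c(7, 79)),
               class = "sy_degenerate_data_error")
  prof <- random_profiles(10, 1)
  sc <- scale_profiles(prof, 0.975)
  expect_equal(sc$p_undiag_dm, prof$p_undiag_dm * 0.975)
  expect_equal(sc$p_total_predm, prof$p_total_predm)
})
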