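test_that("generation is bit-reproducible given seed and config", {
  cfg <- scenario_config(population_size = 1500, seed = 99)
  expect_identical(generate_model_survey(cfg), generate_model_survey(cfg))
  expect_identical(generate_projection_survey(cfg),
                   generate_projection_survey(cfg))
  # different seed differs
  cfg2 <- scenario_config(population_size = 1500, seed = 100)
  expect_false(identical(generate_model_survey(cfg),
                         generate_model_survey(cfg2)))
})

test_that("all-zero polytomous model yields equal latent-state shares", {
  cfg <- scenario_config(population_size = 30000, seed = 5,
                         true_model = flat_true_coefficients())
  sv <- generate_model_survey(cfg)
  shares <- table(sv$latent_state) / nrow(sv)
  expect_true(all(abs(shares - 1 / 3) < 0.02))
})

test_that("default diagnosis model leaves about 90% of prediabetes undetected", {
  sv <- generate_model_survey(scenario_config(population_size = 30000, seed = 8))
  pre <- sv[sv$latent_state == "prediabetes", ]
  undetected <- mean(pre$diagnosed_prediabetes == 0)
  expect_gt(undetected, 0.87)
  expect_lt(undetected, 0.93)
})

test_that("lab values fall inside each latent category's defining range", {
  sv <- generate_model_survey(scenario_config(population_size = 20000, seed = 3))
  ranges <- list(
    hba1c = list(normal = c(0, 5.7), prediabetes = c(5.7, 6.4),
                 diabetes = c(6.5, 14)),
    fpg = list(normal = c(0, 100), prediabetes = c(100, 125),
               diabetes = c(126, 300)),
    ogtt_2h = list(normal = c(0, 140), prediabetes = c(140, 199),
                   diabetes = c(200, 400))
  )
  for (test in names(ranges)) {
    for (st in names(ranges[[test]])) {
      v <- sv[[test]][sv$latent_state == st]
      v <- v[!is.na(v)]
      rng <- ranges[[test]][[st]]
      expect_true(all(v >= rng[1] & v <= rng[2]),
                  label = sprintf("%s within %s range", test, st))
    }
  }
  # with no discordance, classification recovers the latent category exactly
  expect_equal(classify_lab(sv$hba1c, sv$fpg, sv$ogtt_2h),
               as.character(sv$latent_state))
})

test_that("lab-panel assignment rates match the configuration", {
  sv <- generate_model_survey(scenario_config(population_size = 30000, seed = 4))
  expect_equal(mean(!is.na(sv$hba1c)), 1.0)
  expect_lt(abs(mean(!is.na(sv$fpg)) - 0.48), 0.01)
  expect_lt(abs(mean(!is.na(sv$ogtt_2h)) - 0.31), 0.01)
  # every record classifiable
  expect_true(all(!is.na(sv$hba1c) | !is.na(sv$fpg) | !is.na(sv$ogtt_2h)))
})

test_that("covariate marginals converge to the configured mixtures", {
  cfg <- scenario_config(population_size = 50000, seed = 12)
  sv <- generate_model_survey(cfg)
  cs <- cfg$covariate_spec
  for (pair in list(list(sv$age_band, cs$age_probs),
                    list(sv$race_eth, cs$race_probs),
                    list(sv$survey_wave, cs$wave_probs))) {
    obs <- table(factor(pair[[1]], levels = names(pair[[2]])))
    pv <- suppressWarnings(stats::chisq.test(obs, p = pair[[2]])$p.value)
    expect_gt(pv, 0.01)
  }
  expect_true(all(sv$weight > 0))
})

test_that("visit counts follow the configured risk link", {
  vs_flat <- default_visit_spec()
  vs_flat$base[] <- c(1, 2, 0.5, 0.3, 0.2)
  vs_flat$risk_slope[] <- 0
  cfg <- scenario_config(population_size = 20000, seed = 21,
                         visit_spec = vs_flat)
  pv <- generate_projection_survey(cfg)
  tot <- pv$primary_care_office + pv$non_primary_office + pv$outpatient +
    pv$emergency + pv$inpatient_admissions
  expect_lt(abs(mean(tot) - 4.0), 0.1)

  # monotone link: high-risk band visits exceed low-risk band visits
  cfg2 <- scenario_config(population_size = 30000, seed = 22)
  pv2 <- generate_projection_survey(cfg2)
  X <- build_design_matrix(pv2)
  tm <- cfg2$true_model
  P <- screenyield:::softmax3(drop(X %*% tm$prediabetes),
                              drop(X %*% tm$diabetes))
  p_udm <- P[, 3] * (1 - stats::plogis(drop(X %*% tm$diagnosed_dm)))
  tot2 <- pv2$primary_care_office + pv2$non_primary_office + pv2$outpatient +
    pv2$emergency + pv2$inpatient_admissions
  m_low <- mean(tot2[p_udm < 0.05])
  m_high <- mean(tot2[p_udm >= 0.10])
  # oracle: configured means over the same records
  vs <- cfg2$visit_spec
  mu <- rowSums(sapply(names(vs$base),
                       function(v) vs$base[[v]] + vs$risk_slope[[v]] * p_udm))
  expect_gt(m_high, m_low)
  expect_lt(abs(m_low - mean(mu[p_udm < 0.05])), 0.2)
  expect_lt(abs(m_high - mean(mu[p_udm >= 0.10])), 3.0)
})

test_that("zero-inflation of 1 degenerates all visit counts to zero", {
  vs <- default_visit_spec()
  vs$zero_inflation <- 1
  pv <- generate_projection_survey(
    scenario_config(population_size = 500, seed = 2, visit_spec = vs))
  expect_true(all(pv$primary_care_office == 0 & pv$non_primary_office == 0 &
                    pv$outpatient == 0 & pv$emergency == 0 &
                    pv$inpatient_admissions == 0))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(scenario_config(population_size = 0), "population_size",
               class = "sy_config_error")
  bad_cs <- default_covariate_spec()
  bad_cs$age_probs[1] <- bad_cs$age_probs[1] + 0.05
  expect_error(scenario_config(covariate_spec = bad_cs), "age_probs",
               class = "sy_config_error")
  expect_error(scenario_config(lab_assignment = c(hba1c = 1.2, fpg = 0.5,
                                                  ogtt = 0.3)),
               "lab_assignment", class = "sy_config_error")
  bad_vs <- default_visit_spec()
  bad_vs$dispersion <- -1
  expect_error(scenario_config(visit_spec = bad_vs), "dispersion",
               class = "sy_config_error")
})

test_that("discordance switch lets assigned tests disagree with the latent state", {
  cfg <- scenario_config(population_size = 5000, seed = 31,
                         discordance_rate = 0.5)
  sv <- generate_model_survey(cfg)
  lab <- classify_lab(sv$hba1c, sv$fpg, sv$ogtt_2h)
  expect_gt(mean(lab != sv$latent_state), 0.1)
})
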