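# Synthetic cohort generator: covariate marginals, hazard calibration,
# survival/censoring sampling, missingness, and prediction simulation.

test_that("sampled covariates match the configured marginals", {
  co <- sample_covariates(sim_config(), seed = 4)
  expect_identical(nrow(co), 356L)
  expect_lt(abs(mean(co$sex == "female") - 0.52), 0.06)

  big <- sample_covariates(sim_config(n_patients = 100000), seed = 4)
  expect_lt(abs(mean(big$ecog <= 2) - 0.79), 0.005)

  cs <- default_covariate_spec()
  cs$tumor_weights <- c(lung = 1.0)
  one <- sample_covariates(sim_config(covariate_spec = cs), seed = 4)
  expect_true(all(one$primary_tumor == "lung"))

  cs$tumor_weights <- c(lung = 0.5, breast = 0.4)
  expect_error(sim_config(covariate_spec = cs), "sum to 1")
})

test_that("marginal hazard calibration matches the closed form", {
  cfg <- sim_config(n_patients = 100, horizons = c(1, 3),
                    target_mortality = c(0.05, 0.18),
                    target_ascertained = c(100, 100))
  hz <- calibrate_baseline_hazards(cfg)
  expect_equal(hz$death[1], -log(0.95) / 1, tolerance = 1e-12)
  expect_equal(hz$death[2], -(log(0.82) - log(0.95)) / 2,
               tolerance = 1e-12)
  expect_equal(hz$dropout, c(0, 0), tolerance = 1e-12)
})

test_that("zero mortality targets give zero death hazards", {
  cfg <- sim_config(n_patients = 50, horizons = c(1, 3),
                    target_mortality = c(0, 0),
                    target_ascertained = c(50, 45))
  hz <- calibrate_baseline_hazards(cfg)
  expect_equal(hz$death, c(0, 0))
  expect_true(all(hz$dropout >= 0))
})

test_that("covariate-linked solve with zero coefficients reduces to marginal", {
  cfg <- sim_config(n_patients = 200)
  marg <- calibrate_baseline_hazards(cfg)
  linked <- calibrate_baseline_hazards(cfg, eta = rep(0, 200))
  expect_equal(linked$death, marg$death, tolerance = 1e-7)
  expect_equal(linked$dropout, marg$dropout, tolerance = 1e-7)
})

test_that("config validation rejects malformed targets", {
  expect_error(sim_config(target_mortality = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)),
               "non-decreasing")
  expect_error(sim_config(target_ascertained = c(300, 310, 320, 330, 340, 356)),
               "non-increasing")
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(missingness = c(bun = 1.2)), "\\[0,1\\)")
})

test_that("sampled survival respects administrative censoring and dropout", {
  cfg <- sim_config(n_patients = 500)
  sim <- generate_cohort(cfg, seed = 21)
  expect_true(all(sim$cohort$survival_months <= 24))

  # zero dropout: every horizon fully ascertained up to deaths
  cfg0 <- sim_config(n_patients = 500,
                     target_ascertained = rep(500, 6))
  sim0 <- generate_cohort(cfg0, seed = 21)
  expect_equal(hz <- sim0$hazards$dropout, rep(0, 6))
  counts <- ascertainment_counts(sim0$cohort, cfg0$horizons)
  expect_true(all(counts == 500))
})

test_that("latent true survival is non-increasing in horizon", {
  sim <- generate_cohort(frailty_config(300), seed = 13)
  expect_true(all(apply(sim$truth$surv, 1, function(p) all(diff(p) < 0))))
  expect_true(all(sim$truth$surv > 0 & sim$truth$surv < 1))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- frailty_config(150)
  specs <- list(pred_sim_spec("m", shift = 0.3, slope = 1, noise_sd = 0.4))
  s1 <- generate_cohort(cfg, specs, seed = 77)
  s2 <- generate_cohort(cfg, specs, seed = 77)
  expect_identical(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  expect_identical(s1$predictions$m$values, s2$predictions$m$values)
  expect_identical(s1$truth$surv, s2$truth$surv)
})

test_that("identity prediction spec reproduces the truth exactly", {
  sim <- generate_cohort(frailty_config(200),
                         list(pred_sim_spec("id", shift = 0, slope = 1,
                                            noise_sd = 0)),
                         seed = 31)
  expect_equal(unname(sim$predictions$id$values),
               unname(sim$truth$surv), tolerance = 1e-9)
})

test_that("prediction monotonicity follows the sign of the slope", {
  cfg <- frailty_config(120)
  pos <- generate_cohort(cfg, list(pred_sim_spec("p", slope = 0.8,
                                                 noise_sd = 1)),
                         seed = 8)
  expect_identical(model_consistency(pos$predictions$p)$overall, 1)

  # a negative slope reverses every pair with distinct probabilities;
  # the only reasonable pairs left are exact ties from logistic
  # saturation at extreme logits
  neg <- generate_cohort(cfg, list(pred_sim_spec("n", slope = -1,
                                                 noise_sd = 0.5)),
                         seed = 8)
  mcn <- model_consistency(neg$predictions$n)
  expect_lt(mcn$overall, 0.01)
  v <- neg$predictions$n$values
  ties <- sum(vapply(seq_len(nrow(v)), function(i)
    sum(outer(v[i, ], v[i, ], `==`)[upper.tri(diag(ncol(v)))]),
    numeric(1)))
  expect_identical(mcn$n_reasonable, as.integer(ties))
})

test_that("per-horizon noise can break consistency for MC testing", {
  sim <- generate_cohort(frailty_config(300),
                         list(pred_sim_spec("noisy", noise_sd = 0,
                                            horizon_noise_sd = 2)),
                         seed = 15)
  expect_lt(model_consistency(sim$predictions$noisy)$overall, 1)
})

test_that("solved noise hits a target AUC at the reference horizon", {
  cfg <- frailty_config(50000)
  sim <- generate_cohort(cfg,
                         list(pred_sim_spec("t", target_auc = 0.84,
                                            reference_horizon = 12)),
                         seed = 19)
  sm <- status_matrix(sim$cohort, cfg$horizons)
  auc <- auc_at_horizon(sim$predictions$t$values[, "12"], sm[, "12"],
                        ci_method = "none")$value
  expect_gt(auc, 0.835)
  expect_lt(auc, 0.845)
  expect_error(pred_sim_spec("bad", target_auc = 0.4), "\\(0.5, 1\\]")
})

test_that("an unachievable AUC target is rejected, not silently missed", {
  sim <- generate_cohort(sim_config(n_patients = 2000, frailty_sd = 0.2),
                         seed = 3)
  expect_error(simulate_predictions(sim$truth,
                                    pred_sim_spec("x", target_auc = 0.95),
                                    seed = 3),
               "unachievable")
})

test_that("score mode emits integer quantile bins", {
  sim <- generate_cohort(frailty_config(400),
                         list(pred_sim_spec("s", mode = "score",
                                            n_score_levels = 6,
                                            noise_sd = 0.3)),
                         seed = 23)
  v <- sim$predictions$s$values
  expect_true(all(v == round(v)))
  expect_true(all(v >= 0 & v <= 5))
  expect_identical(sim$predictions$s$mode, "score")
})

test_that("lab missingness matches configured rates", {
  cfg <- sim_config()
  sim <- generate_cohort(cfg, seed = 44)
  n_bun <- sum(is.na(sim$cohort$bun))
  sd_bun <- sqrt(356 * 0.25 * 0.75)
  expect_lt(abs(n_bun - 356 * 0.25), 3 * sd_bun)
  expect_false(anyNA(sim$cohort$hgb))

  cfg0 <- sim_config(missingness = setNames(rep(0, 10), pss_labs()))
  sim0 <- generate_cohort(cfg0, seed = 44)
  expect_false(anyNA(as.data.frame(sim0$cohort)[pss_labs()]))
})

test_that("complete-case yield matches the product of retention rates", {
  rates <- default_missingness()
  p_cc <- prod(1 - rates)
  sim <- generate_cohort(sim_config(), seed = 50)
  n_cc <- nrow(complete_case_subset(sim$cohort))
  sd_cc <- sqrt(356 * p_cc * (1 - p_cc))
  expect_lt(abs(n_cc - 356 * p_cc), 4 * sd_cc)
})

test_that("MAR missingness increases with ECOG but keeps the marginal rate", {
  cfg <- sim_config(n_patients = 20000, mar_ecog = TRUE)
  co <- sample_covariates(cfg, seed = 2)
  co$survival_months <- 1; co$death_observed <- FALSE
  mis <- inject_missingness(co, cfg, seed = 2)
  rate <- mean(is.na(mis$bun))
  expect_lt(abs(rate - 0.25), 0.02)
  lo <- mean(is.na(mis$bun[mis$ecog == 0]))
  hi <- mean(is.na(mis$bun[mis$ecog >= 3]))
  expect_gt(hi, lo)
})
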