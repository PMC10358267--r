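# Discrimination, Brier, calibration, decision curves, consistency.

test_that("horizon AUC matches hand-enumerated and oracle values", {
  status <- c("ALIVE", "ALIVE", "DEAD", "DEAD")
  vals <- c(0.6, 0.3, 0.2, 0.4)
  # pairs: (.6,.2)+ (.6,.4)+ (.3,.2)+ (.3,.4)- -> 3/4
  expect_equal(auc_at_horizon(vals, status, ci_method = "none")$value,
               3 / 4)
  expect_equal(auc_at_horizon(c(0.9, 0.8, 0.1, 0.2), status,
                              ci_method = "none")$value, 1)
  expect_equal(auc_at_horizon(rep(0.5, 4), status,
                              ci_method = "none")$value, 0.5)
  expect_error(auc_at_horizon(vals, rep("DEAD", 4), ci_method = "none"),
               "degenerate outcome")
})

test_that("fast AUC equals the pairwise oracle and is rank-invariant", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    vals <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # with ties
    alive <- runif(n) < runif(1, 0.2, 0.8)
    if (all(alive)) alive[1] <- FALSE
    if (!any(alive)) alive[1] <- TRUE
    status <- ifelse(alive, "ALIVE", "DEAD")
    fast <- auc_at_horizon(vals, status, ci_method = "none")$value
    expect_identical(fast, auc_pairwise_oracle(vals, alive))
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(auc_at_horizon(plogis(5 * vals - 1), status,
                                ci_method = "none")$value, fast)
  }
})

test_that("UNKNOWN statuses are excluded from every metric", {
  status <- c("ALIVE", "UNKNOWN", "DEAD", "UNKNOWN")
  vals <- c(0.9, 0.5, 0.1, 0.4)
  a <- auc_at_horizon(vals, status, ci_method = "none")
  expect_identical(a$n, 2L)
  b <- brier_score(vals, status)
  expect_identical(b$n, 2L)
  expect_equal(b$brier, mean(c((0.9 - 1)^2, (0.1 - 0)^2)))
})

test_that("Brier score behaves at its algebraic anchors", {
  status <- c(rep("ALIVE", 3), rep("DEAD", 2))
  perfect <- c(1, 1, 1, 0, 0)
  expect_equal(brier_score(perfect, status)$brier, 0)
  # constant prevalence prediction attains the null Brier exactly
  pbar <- 3 / 5
  b <- brier_score(rep(pbar, 5), status)
  expect_equal(b$brier, b$null_brier)
  expect_equal(b$null_brier, pbar * (1 - pbar))
  # null Brier from a 167/326 mortality split rounds to 0.25
  st <- c(rep("DEAD", 167), rep("ALIVE", 159))
  expect_equal(round(brier_score(runif(326), st)$null_brier, 2), 0.25)
})

test_that("bootstrap CIs are reproducible and bracket the estimate", {
  set.seed(7)
  vals <- runif(80)
  status <- ifelse(runif(80) < vals, "ALIVE", "DEAD")
  a1 <- auc_at_horizon(vals, status, n_boot = 200, seed = 5)
  a2 <- auc_at_horizon(vals, status, n_boot = 200, seed = 5)
  expect_identical(a1, a2)
  expect_lte(a1$ci_low, a1$value)
  expect_gte(a1$ci_high, a1$value)
})

test_that("log(O:E) follows its closed form and sign convention", {
  # O = E gives log(O:E) = 0
  st <- c(rep("ALIVE", 50), rep("DEAD", 50))
  cal <- calibration_fit(rep(0.5, 100), st, ci_method = "none")
  expect_equal(cal$log_oe$value, 0)
  expect_false(cal$slope_defined)
  expect_true(is.na(cal$slope$value))

  # O = 159 survivors, E = 101.5 expected -> log(159/101.5)
  st2 <- c(rep("ALIVE", 159), rep("DEAD", 167))
  cal2 <- calibration_fit(rep(101.5 / 326, 326), st2, ci_method = "none")
  expect_equal(cal2$O, 159)
  expect_equal(cal2$E, 101.5, tolerance = 1e-9)
  expect_equal(cal2$log_oe$value, log(159 / 101.5), tolerance = 1e-9)
  expect_gt(cal2$log_oe$value, 0)   # fewer expected than observed:
                                    # survival underestimated
})

test_that("calibration recovers a generating shift with the right sign", {
  cfg <- frailty_config(20000, dropout = FALSE)
  sim <- generate_cohort(cfg, list(pred_sim_spec("u", shift = 0.8,
                                                 slope = 1)),
                         seed = 62)
  sm <- status_matrix(sim$cohort, cfg$horizons)
  cal <- calibration_fit(sim$predictions$u$values[, "12"], sm[, "12"],
                         ci_method = "none")
  # the model underestimates survival: positive intercept, positive log(O:E)
  expect_lt(abs(cal$intercept$value - 0.8), 0.1)
  expect_lt(abs(cal$joint_intercept$value - 0.8), 0.1)
  expect_lt(abs(cal$slope$value - 1), 0.1)
  expect_gt(cal$log_oe$value, 0)
})

test_that("calibration curve bins are sane", {
  set.seed(9)
  p <- runif(500)
  st <- ifelse(runif(500) < p, "ALIVE", "DEAD")
  cal <- calibration_fit(p, st, ci_method = "none")
  expect_true(all(cal$curve$observed >= 0 & cal$curve$observed <= 1))
  expect_equal(sum(cal$curve$n), 500)
  expect_false(is.unsorted(cal$curve$predicted))
})

test_that("net benefit matches the hand-enumerated 2x2 table", {
  status <- c("ALIVE", "ALIVE", "DEAD", "DEAD")
  p <- c(0.8, 0.4, 0.6, 0.2)
  dc <- decision_curve(p, status, thresholds = 0.5)
  # risks (.2,.6,.4,.8): positives are patients 2 and 4 -> TP=1, FP=1
  expect_equal(dc$nb_model, 1 / 4 - (0.5 / 0.5) * 1 / 4)
  expect_equal(dc$nb_none, 0)

  dc2 <- decision_curve(p, status, thresholds = 1e-6)
  expect_equal(dc2$nb_all, attr(dc2, "prevalence"), tolerance = 1e-5)
  expect_error(decision_curve(p, status, thresholds = c(0, 0.5)),
               "strictly in")
})

test_that("net benefit is bounded by prevalence; a perfect model dominates", {
  set.seed(12)
  p <- runif(300)
  st <- ifelse(runif(300) < p, "ALIVE", "DEAD")
  dc <- decision_curve(p, st)
  expect_true(all(dc$nb_model <= attr(dc, "prevalence") + 1e-12))
  perfect <- as.numeric(st == "ALIVE")
  dcp <- decision_curve(perfect, st)
  expect_true(all(dcp$nb_model >= dcp$nb_all - 1e-12))
  expect_true(all(abs(dcp$nb_model - attr(dcp, "prevalence")) < 1e-12))
})

test_that("model consistency counts reasonable pairs", {
  m <- matrix(c(0.9, 0.8, 0.5,
                0.7, 0.85, 0.5), 3, 2,
              dimnames = list(c("A", "B", "C"), c(6, 12)))
  # A: 0.9 >= 0.7 ok; B: 0.8 < 0.85 violation; C: tie, reasonable
  mc <- model_consistency(m)
  expect_equal(mc$overall, 2 / 3)
  expect_identical(mc$violations$patient_id, "B")

  mono <- matrix(c(0.9, 0.6, 0.8, 0.5, 0.7, 0.4), 2, 3,
                 dimnames = list(c("A", "B"), c(3, 6, 12)))
  expect_identical(model_consistency(mono)$overall, 1)
  expect_true(all(model_consistency(mono)$pairs$mc == 1))

  expect_error(model_consistency(mono[, 1, drop = FALSE]),
               "2 horizons")
})

test_that("missing cells contribute no pairs", {
  m <- matrix(c(0.9, NA, 0.7, 0.4, 0.6, 0.3), 2, 3,
              dimnames = list(c("A", "B"), c(3, 6, 12)))
  mc <- model_consistency(m)
  # B misses the 3-month cell: contributes only the (6,12) pair
  expect_identical(mc$n_pairs, 4L)
})

test_that("sorting each patient's probabilities restores MC = 1", {
  set.seed(33)
  m <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("P%d", 1:20), c(3, 6, 12)))
  sorted <- t(apply(m, 1, sort, decreasing = TRUE))
  dimnames(sorted) <- dimnames(m)
  expect_identical(model_consistency(sorted)$overall, 1)
})
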