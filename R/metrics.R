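# Performance metrics at fixed horizons: discrimination, Brier vs null,
# logistic-recalibration calibration, log(O:E), decision curves, and
# model consistency. All metrics are complete-case per horizon: patients
# whose status at the horizon is UNKNOWN (censored alive before it) are
# dropped, matching per-horizon ascertainment denominators.

#' A point estimate with confidence interval
#'
#' @param value Point estimate.
#' @param ci_low,ci_high 95% confidence limits (`NA` when not computed).
#' @param n Effective sample size the estimate is based on.
#' @param method Short tag describing estimator and CI machinery.
#' @return A `pss_metric`.
#' @export
metric_estimate <- function(value, ci_low = NA_real_, ci_high = NA_real_,
                            n, method = "") {
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high,
                 n = as.integer(n), method = method),
            class = "pss_metric")
}

#' @export
print.pss_metric <- function(x, ...) {
  cat(sprintf("%.3f (95%% CI %.3f-%.3f), n = %d [%s]\n",
              x$value, x$ci_low, x$ci_high, x$n, x$method))
  invisible(x)
}

# Align predictions and statuses, dropping UNKNOWN and missing cells.
prep_horizon <- function(values, status) {
  stopifnot(length(values) == length(status))
  keep <- !is.na(values) & !is.na(status) & status != "UNKNOWN"
  list(values = values[keep], alive = status[keep] == "ALIVE")
}

#' Horizon discrimination (c-index / AUC)
#'
#' Probability that a randomly chosen patient alive at the horizon received
#' a higher predicted survival value than a randomly chosen patient dead by
#' it, ties counted one half. Rank-based, so raw integer scores work as
#' well as probabilities. The 95% CI is a stratified bootstrap (resampling
#' survivors and non-survivors separately).
#'
#' @param values Predicted survival values (probabilities or scores;
#'   higher = better prognosis).
#' @param status Horizon statuses (`"ALIVE"`/`"DEAD"`/`"UNKNOWN"`), e.g. a
#'   column of [status_matrix()]. `UNKNOWN` and `NA` entries are dropped.
#' @param ci_method `"bootstrap"` or `"none"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return A [metric_estimate()].
#' @export
auc_at_horizon <- function(values, status,
                           ci_method = c("bootstrap", "none"),
                           n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  d <- prep_horizon(values, status)
  if (!any(d$alive) || all(d$alive))
    stop("degenerate outcome at horizon: only one class present",
         call. = FALSE)
  est <- fast_auc(d$values, d$alive)
  lo <- hi <- NA_real_
  if (ci_method == "bootstrap") {
    set.seed(seed)
    ia <- which(d$alive); id <- which(!d$alive)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ia, length(ia), replace = TRUE),
               sample(id, length(id), replace = TRUE))
      fast_auc(d$values[idx], c(rep(TRUE, length(ia)),
                                rep(FALSE, length(id))))
    }, numeric(1))
    qs <- quantile(reps, c(0.025, 0.975), names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  metric_estimate(est, lo, hi, length(d$values),
                  paste0("horizon-auc/", ci_method))
}

#' Brier score with null-model benchmark
#'
#' Mean squared difference between the predicted survival probability and
#' the alive indicator at the horizon, together with the null-model Brier
#' score obtained by predicting the outcome prevalence for every patient:
#' `p_bar * (1 - p_bar)`. A model beats the benchmark when `brier <
#' null_brier`; `improvement = brier - null_brier` (negative is good).
#'
#' @param values Predicted survival probabilities.
#' @param status Horizon statuses; `UNKNOWN`/`NA` dropped.
#' @return A `pss_brier`: list with `brier`, `null_brier`, `improvement`,
#'   `n`.
#' @export
brier_score <- function(values, status) {
  d <- prep_horizon(values, status)
  if (any(d$values < 0 | d$values > 1))
    stop("Brier score requires survival probabilities in [0,1]",
         call. = FALSE)
  alive <- as.numeric(d$alive)
  pbar <- mean(alive)
  brier <- mean((d$values - alive)^2)
  null_brier <- pbar * (1 - pbar)
  structure(list(brier = brier, null_brier = null_brier,
                 improvement = brier - null_brier, n = length(alive)),
            class = "pss_brier")
}

#' @export
print.pss_brier <- function(x, ...) {
  cat(sprintf("Brier %.3f (null %.3f), n = %d\n",
              x$brier, x$null_brier, x$n))
  invisible(x)
}

#' Calibration: intercept, slope, log(O:E), calibration curve
#'
#' Logistic recalibration of the alive indicator on the logit of predicted
#' survival. The slope is the coefficient of `logit(p_hat)` in the
#' recalibration fit (1 is ideal; below 1 means predictions too extreme);
#' the intercept is calibration-in-the-large, fitted with `logit(p_hat)`
#' as a fixed offset (0 is ideal; positive means survival is
#' underestimated). Also returns `log(O/E)` — observed over expected
#' survivors, `E = sum(p_hat)` — with a delta-method CI
#' `+/- 1.96 sqrt((1 - p_bar)/O)`, and a decile calibration curve.
#'
#' @param values Predicted survival probabilities.
#' @param status Horizon statuses; `UNKNOWN`/`NA` dropped.
#' @param clamp_eps Probabilities are clamped to `[eps, 1 - eps]` before
#'   the logit (default 1e-6).
#' @param ci_method `"bootstrap"` (stratified, for intercept/slope) or
#'   `"none"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A `pss_calibration`: `intercept`, `slope`, `log_oe` (each a
#'   [metric_estimate()]), `joint_intercept` (the intercept of the joint
#'   recalibration fit, which — unlike calibration-in-the-large — equals
#'   the generating shift even when the slope differs from 1, so it is the
#'   quantity parameter-recovery checks target), `O`, `E`, `curve` (data
#'   frame: bin midpoint, observed fraction alive, bin n), `n`. With
#'   constant predictions the slope is undefined (`NA`) but intercept and
#'   log(O:E) are returned.
#' @export
calibration_fit <- function(values, status, clamp_eps = 1e-6,
                            ci_method = c("bootstrap", "none"),
                            n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  d <- prep_horizon(values, status)
  if (any(d$values < 0 | d$values > 1))
    stop("calibration requires survival probabilities in [0,1]",
         call. = FALSE)
  n <- length(d$values)
  p <- pmin(pmax(d$values, clamp_eps), 1 - clamp_eps)
  lp <- qlogis(p)
  alive <- as.numeric(d$alive)
  slope_defined <- length(unique(p)) >= 2
  fit_ab <- function(lp, alive) {
    a <- coef(suppressWarnings(
      glm(alive ~ 1 + offset(lp), family = binomial())))[[1L]]
    if (slope_defined) {
      jf <- coef(suppressWarnings(
        glm(alive ~ lp, family = binomial())))
      c(a, jf[[2L]], jf[[1L]])
    } else c(a, NA_real_, NA_real_)
  }
  ab <- fit_ab(lp, alive)
  O <- sum(alive); E <- sum(p)
  log_oe <- log(O / E)
  pbar <- O / n
  se_oe <- sqrt((1 - pbar) / O)
  ci <- matrix(NA_real_, 2L, 2L)
  if (ci_method == "bootstrap") {
    set.seed(seed)
    ia <- which(d$alive); id <- which(!d$alive)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ia, length(ia), replace = TRUE),
               sample(id, length(id), replace = TRUE))
      fit_ab(lp[idx], alive[idx])
    }, numeric(3))
    ci[1L, ] <- quantile(reps[1L, ], c(0.025, 0.975), names = FALSE)
    if (slope_defined)
      ci[2L, ] <- quantile(reps[2L, ], c(0.025, 0.975), names = FALSE,
                           na.rm = TRUE)
  }
  qs <- unique(quantile(p, probs = seq(0, 1, 0.1)))
  curve <- if (length(qs) < 2L) {
    data.frame(predicted = mean(p), observed = mean(alive), n = n)
  } else {
    bin <- cut(p, breaks = qs, include.lowest = TRUE, labels = FALSE)
    do.call(rbind, lapply(sort(unique(bin)), function(g) {
      data.frame(predicted = mean(p[bin == g]),
                 observed = mean(alive[bin == g]),
                 n = sum(bin == g))
    }))
  }
  structure(list(
    intercept = metric_estimate(ab[1L], ci[1L, 1L], ci[1L, 2L], n,
                                paste0("offset-logistic/", ci_method)),
    slope = metric_estimate(ab[2L], ci[2L, 1L], ci[2L, 2L], n,
                            paste0("logistic-recalibration/", ci_method)),
    joint_intercept = metric_estimate(ab[3L], NA_real_, NA_real_, n,
                                      "joint-recalibration"),
    log_oe = metric_estimate(log_oe, log_oe - 1.96 * se_oe,
                             log_oe + 1.96 * se_oe, n, "log-oe/delta"),
    O = O, E = E, slope_defined = slope_defined, curve = curve, n = n),
    class = "pss_calibration")
}

#' @export
print.pss_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: intercept %.2f, slope %s, log(O:E) %.2f (O = %d, E = %.1f), n = %d\n",
    x$intercept$value,
    if (x$slope_defined) sprintf("%.2f", x$slope$value) else "undefined",
    x$log_oe$value, x$O, x$E, x$n))
  invisible(x)
}

#' Decision curve (net benefit) at a horizon
#'
#' Net benefit of basing the surgical decision on the model across a grid
#' of threshold probabilities, against the default strategies of treating
#' all or no patients. The event is death by the horizon; predicted risk is
#' `1 - p_hat`; a patient is classified positive when risk >= threshold;
#' `nb = TP/n - FP/n * p_t/(1 - p_t)`.
#'
#' @param values Predicted survival probabilities.
#' @param status Horizon statuses; `UNKNOWN`/`NA` dropped.
#' @param thresholds Grid of threshold probabilities in (0, 1); default
#'   0.01 to 0.99 by 0.01.
#' @param horizon Optional horizon label (months) carried in the result.
#' @return A `pss_dca` data frame: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`; attributes `n`, `prevalence` (death), `horizon`.
#' @export
decision_curve <- function(values, status,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           horizon = NA_real_) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)", call. = FALSE)
  d <- prep_horizon(values, status)
  if (any(d$values < 0 | d$values > 1))
    stop("decision curves require survival probabilities in [0,1]",
         call. = FALSE)
  n <- length(d$values)
  dead <- !d$alive
  prev <- mean(dead)
  risk <- 1 - d$values
  nb_model <- vapply(thresholds, function(pt) {
    pos <- risk >= pt
    tp <- sum(pos & dead) / n
    fp <- sum(pos & !dead) / n
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0)
  attr(out, "n") <- n
  attr(out, "prevalence") <- prev
  attr(out, "horizon") <- horizon
  class(out) <- c("pss_dca", "data.frame")
  out
}

#' Model consistency across horizons
#'
#' Fraction of within-patient prediction pairs that respect the law of
#' attrition by time: for horizons `t1 < t2`, a pair is reasonable iff
#' `p_hat(t1) >= p_hat(t2)` (equal probabilities count as reasonable). A
#' patient contributes a pair only when both cells are present. Reported
#' per ordered horizon pair and overall (total reasonable / total pairs),
#' with the violating records listed for inspection.
#'
#' @param pred A probability-mode `pss_predictions` (a score-mode set with
#'   an attached score map is converted first), or a numeric matrix with
#'   horizon column names.
#' @return A `pss_consistency`: `pairs` data frame (`t1`, `t2`,
#'   `reasonable`, `total`, `mc`), `overall`, `n_reasonable`, `n_pairs`,
#'   `violations` data frame.
#' @export
model_consistency <- function(pred) {
  if (inherits(pred, "pss_predictions")) {
    if (pred$mode == "score") {
      if (is.null(pred$score_map))
        stop("model consistency requires survival probabilities; ",
             "score-mode set has no score map", call. = FALSE)
      pred <- apply_score_map(pred)
    }
    m <- pred$values
  } else {
    m <- as.matrix(pred)
  }
  hs <- as.numeric(colnames(m))
  if (length(hs) < 2L)
    stop("MC requires >= 2 horizons", call. = FALSE)
  pairs <- list(); viol <- list()
  for (i in seq_len(ncol(m) - 1L)) for (j in (i + 1L):ncol(m)) {
    both <- !is.na(m[, i]) & !is.na(m[, j])
    ok <- m[both, i] >= m[both, j]
    pairs[[length(pairs) + 1L]] <-
      data.frame(t1 = hs[i], t2 = hs[j], reasonable = sum(ok),
                 total = sum(both),
                 mc = if (sum(both)) mean(ok) else NA_real_)
    if (any(!ok))
      viol[[length(viol) + 1L]] <- data.frame(
        patient_id = rownames(m)[both][!ok], t1 = hs[i], t2 = hs[j],
        p1 = m[both, i][!ok], p2 = m[both, j][!ok])
  }
  pairs <- do.call(rbind, pairs)
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(patient_id = character(), t1 = numeric(),
                    t2 = numeric(), p1 = numeric(), p2 = numeric())
  rownames(violations) <- NULL
  structure(list(pairs = pairs, overall = sum(pairs$reasonable) /
                   sum(pairs$total),
                 n_reasonable = sum(pairs$reasonable),
                 n_pairs = sum(pairs$total), violations = violations),
            class = "pss_consistency")
}

#' @export
print.pss_consistency <- function(x, ...) {
  cat(sprintf("Model consistency %.3f (%d/%d reasonable pairs)\n",
              x$overall, x$n_reasonable, x$n_pairs))
  invisible(x)
}
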