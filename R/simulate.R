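# Synthetic cohort generator: covariate sampling, piecewise-exponential
# death/dropout hazards calibrated to printed horizon mortality and
# ascertainment targets, lab missingness, and synthetic prediction models
# with controllable discrimination and calibration.

#' Default covariate distributions for the synthetic cohort
#'
#' Marginals emulating a surgical extremity-metastasis cohort: median age 61
#' (range 25-95), 52% female, median BMI 23 (range 13-39), 60% with an extra
#' Charlson comorbidity, ECOG 0-2 with probability 0.79, primary tumor mix
#' lung 33% / breast 16% / hepatocellular 10% / other 41%. Fields not taken
#' from a published summary (treatment history, metastasis sites, ASA mix,
#' lab marginals) are physiologic placeholders, documented as such.
#'
#' @return Named list of distribution parameters; see [sample_covariates()].
#' @export
default_covariate_spec <- function() {
  list(
    age = list(mean = 61, sd = 14, min = 25, max = 95),
    female = 0.52,
    bmi = list(mean = 23, sd = 4.5, min = 13, max = 39),
    charlson = 0.60,
    prior_systemic = 0.55,
    prior_radiation = 0.25,
    visceral_mets = 0.45,
    brain_mets = 0.08,
    lymph_node_mets = 0.30,
    multiple_bone_mets = 0.70,
    complete_fracture = 0.55,
    # P(ECOG 0-2) = 0.20 + 0.33 + 0.26 = 0.79
    ecog_probs = c(`0` = 0.20, `1` = 0.33, `2` = 0.26, `3` = 0.15, `4` = 0.06),
    asa_probs = c(`1` = 0.02, `2` = 0.30, `3` = 0.55, `4` = 0.12, `5` = 0.01),
    tumor_weights = c(lung = 0.33, breast = 0.16, hepatocellular = 0.10,
                      other = 0.41),
    labs = default_lab_spec(),
    # Gaussian-copula correlation between labs, in pss_labs() order
    lab_correlation = diag(10)
  )
}

#' Default lab marginals (placeholders)
#'
#' Normal or log-normal marginals with physiologically plausible location
#' and spread for an advanced-cancer surgical population. These are
#' placeholders, not published summaries; exact lab realism is immaterial
#' to metric correctness and they are fully configurable.
#'
#' @return Named list over [pss_labs()] of `list(dist, ...)` entries.
#' @export
default_lab_spec <- function() {
  list(
    na  = list(dist = "normal",    mean = 137,  sd = 4),
    ca  = list(dist = "normal",    mean = 9.3,  sd = 0.9),
    alb = list(dist = "normal",    mean = 3.6,  sd = 0.6),
    alp = list(dist = "lognormal", meanlog = log(120), sdlog = 0.6),
    bun = list(dist = "lognormal", meanlog = log(16),  sdlog = 0.45),
    hgb = list(dist = "normal",    mean = 11.5, sd = 1.9),
    alc = list(dist = "lognormal", meanlog = log(1.3), sdlog = 0.5),
    anc = list(dist = "lognormal", meanlog = log(5.0), sdlog = 0.5),
    wbc = list(dist = "lognormal", meanlog = log(7.5), sdlog = 0.45),
    plt = list(dist = "normal",    mean = 230,  sd = 90)
  )
}

#' Default per-lab missingness rates
#'
#' Fractions of patients with each lab unrecorded: sodium 0.3%, absolute
#' lymphocyte and neutrophil counts 2.2%, calcium 2.2%, alkaline phosphatase
#' 5%, albumin 7%, blood urea nitrogen 25%; the remaining labs complete.
#'
#' @return Named numeric vector over [pss_labs()].
#' @export
default_missingness <- function() {
  c(na = 0.003, ca = 0.022, alb = 0.070, alp = 0.050, bun = 0.25,
    hgb = 0, alc = 0.022, anc = 0.022, wbc = 0, plt = 0)
}

#' Simulation configuration
#'
#' Parameterizes the synthetic cohort: size, horizons, per-horizon mortality
#' among ascertained patients and ascertainment counts, administrative
#' censoring, covariate/lab marginals, per-lab missingness, and the
#' covariate-hazard link. The defaults are the study conditions the
#' generator emulates: n = 356; horizons 1/3/6/12/18/24 months; mortality
#' 5/18/32/51/61/68%; ascertainment 356/350/342/326/314/302; censoring at
#' 24 months.
#'
#' @param n_patients Cohort size.
#' @param horizons Strictly increasing horizons in months.
#' @param target_mortality Per-horizon deaths/ascertained fractions,
#'   strictly increasing.
#' @param target_ascertained Per-horizon ascertained counts (on the scale of
#'   `n_patients`), non-increasing; converted internally to fractions.
#' @param admin_censor Administrative censoring month.
#' @param hazard_link `"marginal"` (baseline hazards only) or
#'   `"covariate_linked"` (proportional-hazards linear predictor).
#' @param coefficients Named list of per-covariate log hazard ratios (see
#'   [linear_predictor()]); `NULL` means all zero.
#' @param frailty_sd SD of a patient-level normal frailty added to the log
#'   hazard; 0 (default) disables it. A positive value induces between-
#'   patient heterogeneity in true survival probabilities, which synthetic
#'   prediction models need in order to discriminate.
#' @param covariate_spec See [default_covariate_spec()].
#' @param missingness Named per-lab missingness rates in `[0, 1)`.
#' @param mar_ecog If `TRUE`, lab missingness probability increases with
#'   ECOG (missing-at-random) while keeping the configured marginal rate;
#'   default is missing-completely-at-random.
#' @return A `pss_sim_config`.
#' @export
sim_config <- function(n_patients = 356,
                       horizons = c(1, 3, 6, 12, 18, 24),
                       target_mortality = c(0.05, 0.18, 0.32, 0.51, 0.61, 0.68),
                       target_ascertained = c(356, 350, 342, 326, 314, 302),
                       admin_censor = 24,
                       hazard_link = c("marginal", "covariate_linked"),
                       coefficients = NULL,
                       frailty_sd = 0,
                       covariate_spec = default_covariate_spec(),
                       missingness = default_missingness(),
                       mar_ecog = FALSE) {
  hazard_link <- match.arg(hazard_link)
  if (n_patients <= 0) stop("n_patients must be positive", call. = FALSE)
  if (is.unsorted(horizons, strictly = TRUE))
    stop("horizons must be strictly increasing", call. = FALSE)
  if (length(target_mortality) != length(horizons) ||
      length(target_ascertained) != length(horizons))
    stop("targets must have one entry per horizon", call. = FALSE)
  if (is.unsorted(target_mortality))
    stop("target_mortality must be non-decreasing", call. = FALSE)
  if (any(diff(target_ascertained) > 0))
    stop("target_ascertained must be non-increasing", call. = FALSE)
  if (any(target_mortality < 0 | target_mortality > 1))
    stop("target_mortality must lie in [0,1]", call. = FALSE)
  if (max(horizons) > admin_censor)
    stop("horizons must not exceed admin_censor", call. = FALSE)
  if (any(missingness < 0 | missingness >= 1))
    stop("missingness rates must lie in [0,1)", call. = FALSE)
  w <- covariate_spec$tumor_weights
  if (abs(sum(w) - 1) > 1e-8)
    stop("tumor mixture weights must sum to 1", call. = FALSE)
  asc_frac <- target_ascertained / max(target_ascertained)
  structure(list(
    n_patients = n_patients, horizons = horizons,
    target_mortality = target_mortality,
    target_ascertained = target_ascertained,
    ascertained_frac = asc_frac,
    admin_censor = admin_censor, hazard_link = hazard_link,
    coefficients = coefficients, frailty_sd = frailty_sd,
    covariate_spec = covariate_spec, missingness = missingness,
    mar_ecog = mar_ecog), class = "pss_sim_config")
}

rtruncnorm1 <- function(n, mean, sd, min, max) {
  lo <- pnorm(min, mean, sd)
  hi <- pnorm(max, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Sample covariates and labs for a synthetic cohort
#'
#' Draws `n_patients` records from the configured marginals; labs are drawn
#' through a Gaussian copula with the configured correlation matrix
#' (identity by default), truncated below at zero. Survival fields are not
#' yet present (see [sample_survival_and_censoring()]).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `pss_cohort` (provenance `"synthetic"`) without survival
#'   columns.
#' @export
sample_covariates <- function(config, seed = 1) {
  stopifnot(inherits(config, "pss_sim_config"))
  set.seed(seed)
  cs <- config$covariate_spec
  n <- config$n_patients
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = rtruncnorm1(n, cs$age$mean, cs$age$sd, cs$age$min, cs$age$max),
    sex = ifelse(runif(n) < cs$female, "female", "male"),
    bmi = rtruncnorm1(n, cs$bmi$mean, cs$bmi$sd, cs$bmi$min, cs$bmi$max),
    charlson = runif(n) < cs$charlson,
    prior_systemic = runif(n) < cs$prior_systemic,
    prior_radiation = runif(n) < cs$prior_radiation,
    visceral_mets = runif(n) < cs$visceral_mets,
    brain_mets = runif(n) < cs$brain_mets,
    lymph_node_mets = runif(n) < cs$lymph_node_mets,
    n_bone_mets = ifelse(runif(n) < cs$multiple_bone_mets,
                         "multiple", "single"),
    fracture_status = ifelse(runif(n) < cs$complete_fracture,
                             "complete", "impending"),
    ecog = sample(0:4, n, replace = TRUE, prob = cs$ecog_probs),
    asa = sample(1:5, n, replace = TRUE, prob = cs$asa_probs),
    primary_tumor = sample(names(cs$tumor_weights), n, replace = TRUE,
                           prob = cs$tumor_weights),
    stringsAsFactors = FALSE)
  labs <- pss_labs()
  R <- cs$lab_correlation
  z <- MASS::mvrnorm(n, mu = rep(0, length(labs)), Sigma = R)
  u <- pnorm(z)
  for (j in seq_along(labs)) {
    sp <- cs$labs[[labs[j]]]
    df[[labs[j]]] <- if (sp$dist == "lognormal") {
      qlnorm(u[, j], sp$meanlog, sp$sdlog)
    } else {
      # truncate the normal marginal at zero: labs are non-negative
      lo <- pnorm(0, sp$mean, sp$sd)
      qnorm(lo + u[, j] * (1 - lo), sp$mean, sp$sd)
    }
  }
  as_pss_cohort(df, "synthetic")
}

#' Proportional-hazards linear predictor from named coefficients
#'
#' Builds `sum_j beta_j x_j` over cohort columns. Logical covariates enter
#' as 0/1; `sex` as male = 1; `n_bone_mets` as multiple = 1;
#' `fracture_status` as complete = 1; `age`, `bmi`, `ecog`, `asa` and labs
#' as recorded.
#'
#' @param cohort A cohort table.
#' @param coefficients Named list/vector of log hazard ratios; `NULL` gives
#'   all zeros.
#' @return Numeric vector of length `nrow(cohort)`.
#' @export
linear_predictor <- function(cohort, coefficients = NULL) {
  eta <- numeric(nrow(cohort))
  if (is.null(coefficients) || !length(coefficients)) return(eta)
  for (v in names(coefficients)) {
    x <- switch(v,
      sex = as.numeric(cohort$sex == "male"),
      n_bone_mets = as.numeric(cohort$n_bone_mets == "multiple"),
      fracture_status = as.numeric(cohort$fracture_status == "complete"),
      {
        if (!v %in% names(cohort))
          stop("unknown covariate in coefficients: ", v, call. = FALSE)
        as.numeric(cohort[[v]])
      })
    eta <- eta + coefficients[[v]] * x
  }
  eta
}

#' Calibrate piecewise-constant death and dropout hazards
#'
#' Solves, per inter-horizon interval, a constant death hazard and a
#' constant dropout (loss to follow-up) hazard so that the expected
#' fraction of observed deaths and the expected ascertained fraction both
#' match the configured targets at every horizon. Mortality targets are
#' interpreted as the study reports them: deaths among ascertained
#' patients. With full ascertainment (no dropout) the solution reduces to
#' the closed form `lambda_k = -(log S(t_k) - log S(t_(k-1))) / delta_k` on
#' the cumulative survival targets.
#'
#' In `covariate_linked` mode (or with a frailty), supply the sampled
#' linear predictors `eta`; baseline hazards are then solved numerically so
#' the population-average deaths and ascertainment match the same targets.
#'
#' @param config A [sim_config()].
#' @param eta Optional numeric vector of per-patient log hazard multipliers
#'   (linear predictor plus frailty). `NULL` uses the marginal closed form.
#' @return A `pss_hazards`: list with `breaks`, per-interval baseline
#'   `death` and `dropout` rates (per month), and the `eta` used.
#' @export
calibrate_baseline_hazards <- function(config, eta = NULL) {
  stopifnot(inherits(config, "pss_sim_config"))
  br <- c(0, config$horizons)
  m <- config$target_mortality
  asc <- config$ascertained_frac
  D <- m * asc          # expected observed-death fraction at each horizon
  SG <- (1 - m) * asc   # expected at-risk (alive & followed) fraction
  if (any(diff(c(1, SG)) > 1e-12))
    stop("infeasible targets: at-risk fraction must be non-increasing",
         call. = FALSE)
  if (any(diff(c(0, D)) < 0))
    stop("infeasible targets: observed deaths must be non-decreasing",
         call. = FALSE)
  K <- length(m)
  lam <- mu <- numeric(K)
  if (is.null(eta)) {
    D0 <- 0; SG0 <- 1
    for (k in seq_len(K)) {
      dt <- br[k + 1L] - br[k]
      theta <- -log(SG[k] / SG0) / dt
      if (theta <= 1e-14) {
        # nothing leaves the risk set in this interval
        if (D[k] - D0 > 1e-12)
          stop(sprintf(
            "infeasible targets in interval (%g, %g]: deaths without attrition",
            br[k], br[k + 1L]), call. = FALSE)
        lam[k] <- 0; mu[k] <- 0
      } else {
        lam[k] <- theta * (D[k] - D0) / (SG0 * (1 - exp(-theta * dt)))
        mu[k] <- theta - lam[k]
        if (mu[k] < -1e-9)
          stop(sprintf(
            "infeasible targets in interval (%g, %g]: implied dropout hazard < 0",
            br[k], br[k + 1L]), call. = FALSE)
        mu[k] <- max(mu[k], 0)
      }
      D0 <- D[k]; SG0 <- SG[k]
    }
  } else {
    w <- exp(eta)
    d_i <- numeric(length(w)); sg_i <- rep(1, length(w))
    step <- function(lam0, mu0, dt) {
      rate <- lam0 * w + mu0
      decay <- exp(-rate * dt)
      frac <- ifelse(rate > 0, (lam0 * w) / rate * (1 - decay), 0)
      list(sg = sg_i * decay, d = d_i + sg_i * frac)
    }
    for (k in seq_len(K)) {
      dt <- br[k + 1L] - br[k]
      solve_lam <- function(mu0) {
        if (D[k] - mean(d_i) <= 1e-14) return(0)
        uniroot(function(l) mean(step(l, mu0, dt)$d) - D[k],
                c(0, 100 / dt), tol = 1e-12)$root
      }
      g <- function(mu0) mean(step(solve_lam(mu0), mu0, dt)$sg) - SG[k]
      if (g(0) < -1e-10)
        stop(sprintf(
          "infeasible targets in interval (%g, %g]: too few survivors even without dropout",
          br[k], br[k + 1L]), call. = FALSE)
      mu[k] <- if (abs(g(0)) < 1e-12) 0 else
        uniroot(g, c(0, 100 / dt), tol = 1e-12)$root
      lam[k] <- solve_lam(mu[k])
      st <- step(lam[k], mu[k], dt)
      d_i <- st$d; sg_i <- st$sg
    }
  }
  structure(list(breaks = br, death = lam, dropout = mu,
                 link = if (is.null(eta)) "marginal" else "covariate_linked",
                 eta = eta),
            class = "pss_hazards")
}

# Cumulative baseline hazard at times t for piecewise-constant rates.
cum_hazard <- function(rates, breaks, t) {
  K <- length(rates)
  H <- c(0, cumsum(rates * diff(breaks)))
  vapply(t, function(tt) {
    k <- findInterval(tt, breaks, rightmost.closed = FALSE)
    if (k > K) H[K + 1L] + rates[K] * (tt - breaks[K + 1L])
    else H[k] + rates[k] * (tt - breaks[k])
  }, numeric(1))
}

# Invert the cumulative baseline hazard: smallest t with H(t) = target.
# Rates beyond the last break continue at the final interval's rate.
invert_cum_hazard <- function(rates, breaks, target) {
  K <- length(rates)
  H <- c(0, cumsum(rates * diff(breaks)))
  out <- rep(Inf, length(target))
  for (k in seq_len(K)) {
    idx <- is.infinite(out) & target <= H[k + 1L] & rates[k] > 0
    out[idx] <- breaks[k] + (target[idx] - H[k]) / rates[k]
    # targets below H[k+1] but rate 0: cannot occur since H flat
  }
  idx <- is.infinite(out) & rates[K] > 0
  out[idx] <- breaks[K + 1L] + (target[idx] - H[K + 1L]) / rates[K]
  out
}

#' Sample survival and censoring times
#'
#' Draws a piecewise-exponential death time (baseline hazard scaled by
#' `exp(eta)` per patient) and an independent piecewise-exponential dropout
#' time; the observed time is the minimum of both and the administrative
#' censoring month. Also returns the latent truth: each patient's true
#' survival probability `p_i(t) = exp(-Lambda_i(t))` at every horizon.
#'
#' @param cohort Covariate cohort from [sample_covariates()].
#' @param hazards A `pss_hazards` from [calibrate_baseline_hazards()].
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @param eta Per-patient log hazard multipliers (default all zero).
#' @return List with `cohort` (survival columns added) and `truth`
#'   (`pss_truth`: survival-probability matrix patients x horizons, and
#'   `eta`).
#' @export
sample_survival_and_censoring <- function(cohort, hazards, config, seed = 1,
                                          eta = NULL) {
  n <- nrow(cohort)
  if (is.null(eta)) eta <- numeric(n)
  stopifnot(length(eta) == n)
  set.seed(seed)
  w <- exp(eta)
  u_death <- rexp(n)
  u_drop <- rexp(n)
  td <- invert_cum_hazard(hazards$death, hazards$breaks, u_death / w)
  tc <- invert_cum_hazard(hazards$dropout, hazards$breaks, u_drop)
  cens <- config$admin_censor
  obs <- pmin(td, tc, cens)
  cohort$survival_months <- obs
  cohort$death_observed <- td <= pmin(tc, cens)
  surv <- outer(w, cum_hazard(hazards$death, hazards$breaks,
                              config$horizons)) # Lambda_i(t_k)
  surv <- exp(-surv)
  dimnames(surv) <- list(cohort$patient_id, config$horizons)
  truth <- structure(list(surv = surv, eta = eta,
                          horizons = config$horizons),
                     class = "pss_truth")
  list(cohort = as_pss_cohort(as.data.frame(cohort), "synthetic"),
       truth = truth)
}

#' Inject lab missingness
#'
#' Blanks each lab independently at the configured rate. Default mechanism
#' is MCAR; with `mar_ecog = TRUE` in the config, a patient's missingness
#' probability scales with `1 + ecog/2`, renormalized so the marginal rate
#' is preserved (missing at random given ECOG).
#'
#' @param cohort Cohort with complete labs.
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @return The cohort with `NA` lab gaps.
#' @export
inject_missingness <- function(cohort, config, seed = 1) {
  set.seed(seed)
  rates <- config$missingness
  n <- nrow(cohort)
  wt <- if (isTRUE(config$mar_ecog)) 1 + cohort$ecog / 2 else rep(1, n)
  wt <- wt / mean(wt)
  for (v in intersect(names(rates), pss_labs())) {
    p <- pmin(rates[[v]] * wt, 0.99)
    cohort[[v]][runif(n) < p] <- NA_real_
  }
  cohort
}

#' Specification of a synthetic prediction model
#'
#' Synthetic predictions are a distorted view of the latent truth:
#' `p_hat_i(t) = expit((logit(p_i(t)) - a - e_i) / b)` with a single
#' patient-level noise term `e_i ~ N(0, sigma^2)` shared across horizons
#' (so within-patient monotonicity — hence model consistency 1 — is
#' preserved whenever `b > 0`). The parameters `(a, b)` are on the
#' recalibration scale: a logistic recalibration of these predictions
#' against outcomes drawn from the truth recovers intercept `a` and slope
#' `b`, and a positive `a` means survival is underestimated, matching the
#' reporting convention for calibration intercepts.
#'
#' @param name Model name.
#' @param target_auc Optional target discrimination at `reference_horizon`:
#'   `sigma` is then solved by bisection (see [simulate_predictions()])
#'   instead of taken from `noise_sd`. Must lie in (0.5, 1].
#' @param reference_horizon Months; horizon at which `target_auc` is
#'   evaluated.
#' @param shift Calibration intercept `a` (logit units).
#' @param slope Calibration slope `b`; nonzero. Negative values produce
#'   deliberately inconsistent (anti-monotone) models for testing.
#' @param noise_sd Patient-level noise SD `sigma` (logit units) when
#'   `target_auc` is `NULL`.
#' @param horizon_noise_sd Optional per-cell noise SD that deliberately
#'   breaks within-patient monotonicity (for consistency testing).
#' @param mode `"probability"` or `"score"`. Score mode quantile-bins the
#'   latent predictor into `n_score_levels` integers (higher = better
#'   prognosis).
#' @param n_score_levels Number of integer score levels in score mode.
#' @return A `pss_pred_spec`.
#' @export
pred_sim_spec <- function(name, target_auc = NULL, reference_horizon = 12,
                          shift = 0, slope = 1, noise_sd = 0,
                          horizon_noise_sd = 0,
                          mode = c("probability", "score"),
                          n_score_levels = 10) {
  mode <- match.arg(mode)
  if (!is.null(target_auc) && (target_auc <= 0.5 || target_auc > 1))
    stop("target_auc must lie in (0.5, 1]", call. = FALSE)
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  structure(list(name = name, target_auc = target_auc,
                 reference_horizon = reference_horizon, shift = shift,
                 slope = slope, noise_sd = noise_sd,
                 horizon_noise_sd = horizon_noise_sd, mode = mode,
                 n_score_levels = n_score_levels),
            class = "pss_pred_spec")
}

fast_auc <- function(score, alive) {
  r <- rank(score)
  n1 <- sum(alive); n0 <- sum(!alive)
  (sum(r[alive]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

# Solve the patient-level noise SD so the empirical AUC at the reference
# horizon hits the target. Evaluated on the empirical distribution of the
# supplied true probabilities, resampled to `n_eval` patients, with
# outcomes drawn once and a fixed standard-normal noise draw so AUC(sigma)
# is a deterministic, decreasing function amenable to bisection.
solve_noise_sd <- function(p_true, target_auc, n_eval = 50000,
                           tol = 0.005) {
  p <- if (length(p_true) >= n_eval) p_true
       else sample(p_true, n_eval, replace = TRUE)
  alive <- runif(length(p)) < p
  if (all(alive) || !any(alive))
    stop("degenerate outcome at the reference horizon", call. = FALSE)
  e0 <- rnorm(length(p))
  lp <- qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  f <- function(sig) fast_auc(lp - sig * e0, alive)
  if (f(0) < target_auc - tol)
    stop(sprintf(
      "target_auc %.3f unachievable: noise-free AUC of the truth is %.3f",
      target_auc, f(0)), call. = FALSE)
  lo <- 0; hi <- 0.5
  while (f(hi) > target_auc && hi < 64) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    a <- f(mid)
    if (abs(a - target_auc) <= tol / 2) return(mid)
    if (a > target_auc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a prediction model from the latent truth
#'
#' Emits one prediction set per [pred_sim_spec()]: the latent true survival
#' probabilities distorted by the configured calibration shift/slope and
#' patient-level noise. When `target_auc` is given, the noise SD is solved
#' by bisection so the empirical AUC at the reference horizon matches the
#' target within 0.005, evaluated at 50,000 patients drawn from the
#' empirical distribution of the truth.
#'
#' @param truth A `pss_truth` from [sample_survival_and_censoring()].
#' @param spec A [pred_sim_spec()].
#' @param seed Integer seed.
#' @return A `pss_predictions`; the solved/used noise SD is attached as
#'   attribute `"noise_sd"`.
#' @export
simulate_predictions <- function(truth, spec, seed = 1) {
  stopifnot(inherits(truth, "pss_truth"), inherits(spec, "pss_pred_spec"))
  set.seed(seed)
  p <- truth$surv
  n <- nrow(p)
  sigma <- spec$noise_sd
  if (!is.null(spec$target_auc)) {
    j <- match(spec$reference_horizon, truth$horizons)
    if (is.na(j))
      stop("reference_horizon not among the truth's horizons", call. = FALSE)
    sigma <- solve_noise_sd(p[, j], spec$target_auc)
  }
  eps <- rnorm(n, 0, sigma)
  lp <- qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  latent <- sweep(lp, 1L, eps + spec$shift, `-`)
  if (spec$horizon_noise_sd > 0)
    latent <- latent - matrix(rnorm(length(latent), 0,
                                    spec$horizon_noise_sd),
                              nrow = n)
  latent <- latent / spec$slope
  if (spec$mode == "probability") {
    out <- prediction_set(spec$name, plogis(latent), mode = "probability")
  } else {
    scores <- apply(latent, 2L, function(x) {
      qs <- quantile(x, probs = seq(0, 1, length.out =
                                      spec$n_score_levels + 1L))
      as.numeric(cut(x, breaks = unique(qs), include.lowest = TRUE,
                     labels = FALSE)) - 1
    })
    dimnames(scores) <- dimnames(p)
    out <- prediction_set(spec$name, scores, mode = "score")
  }
  attr(out, "noise_sd") <- sigma
  out
}

#' Generate a full synthetic bundle: cohort, truth, predictions
#'
#' Composes [sample_covariates()], the hazard calibration,
#' [sample_survival_and_censoring()], [inject_missingness()], and
#' [simulate_predictions()] for each prediction spec. Deterministic given
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param pred_specs List of [pred_sim_spec()]s (possibly empty).
#' @param seed Integer seed; sub-stage seeds are derived from it.
#' @return A `pss_simulation`: list with `cohort`, `truth`, `predictions`
#'   (named list), `hazards`, and `config`.
#' @export
generate_cohort <- function(config, pred_specs = list(), seed = 1) {
  stopifnot(inherits(config, "pss_sim_config"))
  if (inherits(pred_specs, "pss_pred_spec")) pred_specs <- list(pred_specs)
  cov <- sample_covariates(config, seed = seed)
  set.seed(seed + 1L)
  eta <- linear_predictor(cov, config$coefficients)
  if (config$frailty_sd > 0)
    eta <- eta + rnorm(nrow(cov), 0, config$frailty_sd)
  use_eta <- config$hazard_link == "covariate_linked" ||
    config$frailty_sd > 0 || any(eta != 0)
  hazards <- calibrate_baseline_hazards(config,
                                        eta = if (use_eta) eta else NULL)
  sv <- sample_survival_and_censoring(cov, hazards, config,
                                      seed = seed + 2L, eta = eta)
  cohort <- inject_missingness(sv$cohort, config, seed = seed + 3L)
  preds <- list()
  for (i in seq_along(pred_specs)) {
    ps <- simulate_predictions(sv$truth, pred_specs[[i]],
                               seed = seed + 10L + i)
    preds[[ps$model]] <- ps
  }
  structure(list(cohort = cohort, truth = sv$truth, predictions = preds,
                 hazards = hazards, config = config, seed = seed),
            class = "pss_simulation")
}
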