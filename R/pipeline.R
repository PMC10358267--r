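# Orchestration: run every metric for every model and horizon, the
# complete-case sensitivity analysis, and report formatting shaped like
# the published comparison tables.

#' Run configuration for a validation
#'
#' @param horizons Evaluation horizons in months (non-empty, increasing).
#' @param n_boot Bootstrap resamples for CIs.
#' @param seed Master seed (bootstraps and imputation derive from it).
#' @param clamp_eps Probability clamp before logits.
#' @param thresholds Decision-curve threshold grid.
#' @param admin_censor Administrative censoring month.
#' @param impute Run missForest-style imputation when labs are missing.
#' @param sensitivity Also run the complete-case sensitivity analysis.
#' @return A `pss_run_config`.
#' @export
run_config <- function(horizons = c(1, 3, 6, 12, 18, 24), n_boot = 2000,
                       seed = 1, clamp_eps = 1e-6,
                       thresholds = seq(0.01, 0.99, by = 0.01),
                       admin_censor = 24, impute = TRUE,
                       sensitivity = TRUE) {
  if (!length(horizons) || is.unsorted(horizons, strictly = TRUE))
    stop("horizons must be non-empty and strictly increasing",
         call. = FALSE)
  structure(list(horizons = horizons, n_boot = n_boot, seed = seed,
                 clamp_eps = clamp_eps, thresholds = thresholds,
                 admin_censor = admin_censor, impute = impute,
                 sensitivity = sensitivity),
            class = "pss_run_config")
}

#' Validate a set of prediction models against a cohort
#'
#' For every model and every available horizon: discrimination (c-index
#' with bootstrap CI) and — for probability-mode models, or score-mode
#' models with a score map — Brier score vs the null model, calibration
#' (intercept, slope, log(O:E)), and the decision curve. Probability-mode
#' models with at least two horizons also get a model-consistency result.
#' Score-only models without a map carry an explicit unavailability reason
#' instead, mirroring the exclusion of such systems from calibration and
#' consistency analysis. When the cohort has missing labs the sensitivity
#' analysis re-runs everything on the complete-case subset.
#'
#' @param cohort A `pss_cohort` with survival fields.
#' @param predictions A `pss_predictions` or (named) list of them.
#' @param config A [run_config()].
#' @return A `pss_report`: per-model results, optional `sensitivity`
#'   report, `imputation` trace, and run `metadata`. Deterministic given
#'   the config seed.
#' @export
run_validation <- function(cohort, predictions, config = run_config()) {
  if (inherits(predictions, "pss_predictions"))
    predictions <- setNames(list(predictions), predictions$model)
  ids <- unique(unlist(lapply(predictions, function(p)
    rownames(p$values))))
  absent <- setdiff(ids, cohort$patient_id)
  if (length(absent))
    stop("prediction patients absent from cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
  imputation <- NULL
  labs_missing <- anyNA(as.data.frame(cohort)[pss_labs()])
  if (config$impute && labs_missing)
    imputation <- impute_missforest(cohort, seed = config$seed)
  sm <- status_matrix(cohort, config$horizons, config$admin_censor)
  models <- lapply(predictions, function(pred) {
    prob_ok <- has_probabilities(pred)
    ppred <- if (pred$mode == "score" && prob_ok) apply_score_map(pred)
             else pred
    hs <- intersect(pred$horizons, config$horizons)
    per_h <- lapply(hs, function(h) {
      hc <- as.character(h)
      v <- pred$values[, hc]
      present <- !is.na(v)
      if (!any(present)) return(NULL)
      st <- sm[rownames(pred$values)[present], hc]
      res <- list(horizon = h,
                  n = sum(present & st != "UNKNOWN", na.rm = TRUE))
      res$auc <- auc_at_horizon(v[present], st, n_boot = config$n_boot,
                                seed = config$seed)
      if (prob_ok) {
        pv <- ppred$values[, hc][present]
        res$brier <- brier_score(pv, st)
        res$calibration <- calibration_fit(pv, st,
                                           clamp_eps = config$clamp_eps,
                                           n_boot = config$n_boot,
                                           seed = config$seed)
        res$dca <- decision_curve(pv, st,
                                  thresholds = config$thresholds,
                                  horizon = h)
      }
      res
    })
    per_h <- Filter(Negate(is.null), per_h)
    names(per_h) <- vapply(per_h, function(x) as.character(x$horizon),
                           character(1))
    out <- list(model = pred$model, mode = pred$mode, horizons = per_h)
    if (prob_ok && length(per_h) >= 2L) {
      keep <- colnames(ppred$values) %in% names(per_h)
      out$consistency <- model_consistency(
        ppred$values[, keep, drop = FALSE])
    }
    if (!prob_ok)
      out$unavailable <-
        "integer-score model without score map: Brier, calibration, DCA and MC unavailable"
    out
  })
  sens <- NULL
  if (config$sensitivity && labs_missing) {
    cc <- complete_case_subset(cohort)
    if (nrow(cc)) {
      sub_preds <- lapply(predictions, function(p) {
        keep <- rownames(p$values) %in% cc$patient_id
        prediction_set(p$model, p$values[keep, , drop = FALSE],
                       mode = p$mode, score_map = p$score_map)
      })
      cfg <- config
      cfg$impute <- FALSE
      cfg$sensitivity <- FALSE
      sens <- run_validation(cc, sub_preds, cfg)
    }
  }
  structure(list(models = models, sensitivity = sens,
                 imputation = imputation,
                 metadata = list(seed = config$seed,
                                 n_boot = config$n_boot,
                                 horizons = config$horizons,
                                 n_patients = nrow(cohort),
                                 version = as.character(
                                   utils::packageVersion("pssval")))),
            class = "pss_report")
}

fmt2 <- function(x) sprintf("%.2f", x)
fmt_ci <- function(m) sprintf("%.2f (%.2f–%.2f)", m$value, m$ci_low,
                              m$ci_high)
DASH <- "–"

#' Format a validation report
#'
#' `style = "table2"` prints, per model and horizon, the c-index as
#' `"0.84 (0.80-0.89)"` and the Brier score as `"0.16 (0.25)"` with the
#' null-model Brier in parentheses; `"table3"` prints calibration
#' intercept/slope/log(O:E) blocks; `"tidy"` emits a long-format data
#' frame. Metrics that are unavailable (score-only model, horizon not
#' predicted) appear as an en dash.
#'
#' @param report A `pss_report`.
#' @param style `"table2"`, `"table3"`, or `"tidy"`.
#' @return A data frame (character cells for the table styles).
#' @export
format_report <- function(report, style = c("table2", "table3", "tidy")) {
  style <- match.arg(style)
  if (style == "tidy") return(tidy_report(report))
  models <- report$models
  hs <- report$metadata$horizons
  cell <- function(mod, h, what) {
    r <- mod$horizons[[as.character(h)]]
    if (is.null(r)) return(DASH)
    switch(what,
      cindex = fmt_ci(r$auc),
      brier = if (is.null(r$brier)) DASH else
        sprintf("%s (%s)", fmt2(r$brier$brier), fmt2(r$brier$null_brier)),
      intercept = if (is.null(r$calibration)) DASH else
        fmt_ci(r$calibration$intercept),
      slope = if (is.null(r$calibration) ||
                  !r$calibration$slope_defined) DASH else
        fmt_ci(r$calibration$slope),
      log_oe = if (is.null(r$calibration)) DASH else
        fmt_ci(r$calibration$log_oe))
  }
  block <- function(what, label) {
    rows <- lapply(hs, function(h) {
      vals <- vapply(models, cell, character(1), h = h, what = what)
      c(metric = label, horizon_months = as.character(h), vals)
    })
    do.call(rbind, rows)
  }
  tab <- if (style == "table2") {
    rbind(block("cindex", "c-index"), block("brier", "Brier score"))
  } else {
    rbind(block("intercept", "calibration intercept"),
          block("slope", "calibration slope"),
          block("log_oe", "log(O:E)"))
  }
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("metric", "horizon_months",
                  vapply(models, `[[`, character(1), "model"))
  rownames(out) <- NULL
  out
}

#' Long-format (tidy) view of a validation report
#'
#' @param report A `pss_report`.
#' @return Data frame: `model`, `horizon_months`, `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
tidy_report <- function(report) {
  rows <- list()
  add <- function(model, h, metric, est, lo = NA_real_, hi = NA_real_,
                  n = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, horizon_months = h, metric = metric, estimate = est,
      ci_low = lo, ci_high = hi, n = n, stringsAsFactors = FALSE)
  }
  for (mod in report$models) {
    for (r in mod$horizons) {
      add(mod$model, r$horizon, "c_index", r$auc$value, r$auc$ci_low,
          r$auc$ci_high, r$auc$n)
      if (!is.null(r$brier)) {
        add(mod$model, r$horizon, "brier", r$brier$brier, n = r$brier$n)
        add(mod$model, r$horizon, "null_brier", r$brier$null_brier,
            n = r$brier$n)
      }
      if (!is.null(r$calibration)) {
        cal <- r$calibration
        add(mod$model, r$horizon, "calibration_intercept",
            cal$intercept$value, cal$intercept$ci_low,
            cal$intercept$ci_high, cal$n)
        if (cal$slope_defined)
          add(mod$model, r$horizon, "calibration_slope", cal$slope$value,
              cal$slope$ci_low, cal$slope$ci_high, cal$n)
        add(mod$model, r$horizon, "log_oe", cal$log_oe$value,
            cal$log_oe$ci_low, cal$log_oe$ci_high, cal$n)
      }
    }
    if (!is.null(mod$consistency))
      add(mod$model, NA_real_, "model_consistency",
          mod$consistency$overall, n = mod$consistency$n_pairs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pss_report <- function(x, ...) {
  cat(sprintf("<pss_report> %d model(s), horizons %s, n = %d\n",
              length(x$models),
              paste(x$metadata$horizons, collapse = "/"),
              x$metadata$n_patients))
  print(format_report(x, "table2"))
  invisible(x)
}

#' Per-horizon mortality summary from counts
#'
#' @param deaths Deaths observed by each horizon.
#' @param ascertained Patients with ascertainable status at each horizon.
#' @param horizons Horizon labels in months.
#' @return Data frame with `horizon_months`, `deaths`, `ascertained`, and
#'   `mortality_pct` (integer percent, `100 * deaths / ascertained`
#'   rounded).
#' @export
mortality_summary <- function(deaths, ascertained,
                              horizons = seq_along(deaths)) {
  stopifnot(length(deaths) == length(ascertained),
            length(horizons) == length(deaths))
  pct <- ifelse(ascertained > 0, round(100 * deaths / ascertained),
                NA_real_)
  data.frame(horizon_months = horizons, deaths = deaths,
             ascertained = ascertained, mortality_pct = pct)
}

#' Descriptive summary of a cohort
#'
#' Per-horizon deaths, ascertained counts and mortality percentages, plus
#' covariate summaries (median/range for age and BMI, category percents).
#'
#' @param cohort A `pss_cohort` with survival fields.
#' @param horizons Horizons in months.
#' @param admin_censor Administrative censoring month.
#' @return A `pss_cohort_summary`: list with `mortality` (data frame) and
#'   `covariates` (named list).
#' @export
summarize_cohort <- function(cohort, horizons = c(1, 3, 6, 12, 18, 24),
                             admin_censor = 24) {
  sm <- status_matrix(cohort, horizons, admin_censor)
  deaths <- apply(sm, 2L, function(x) sum(x == "DEAD", na.rm = TRUE))
  asc <- apply(sm, 2L, function(x) sum(x != "UNKNOWN", na.rm = TRUE))
  mort <- mortality_summary(deaths, asc, horizons)
  cov <- list(
    n = nrow(cohort),
    age = c(median = median(cohort$age), min = min(cohort$age),
            max = max(cohort$age)),
    bmi = c(median = median(cohort$bmi), min = min(cohort$bmi),
            max = max(cohort$bmi)),
    pct_female = 100 * mean(cohort$sex == "female"),
    pct_charlson = 100 * mean(cohort$charlson),
    pct_ecog_0_2 = 100 * mean(cohort$ecog <= 2),
    primary_tumor_pct = 100 * sort(prop.table(table(cohort$primary_tumor)),
                                   decreasing = TRUE))
  structure(list(mortality = mort, covariates = cov),
            class = "pss_cohort_summary")
}

#' @export
print.pss_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients; median age %.0f (range %.0f-%.0f); %.0f%% female\n",
              x$covariates$n, x$covariates$age["median"],
              x$covariates$age["min"], x$covariates$age["max"],
              x$covariates$pct_female))
  print(x$mortality, row.names = FALSE)
  invisible(x)
}
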