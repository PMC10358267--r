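# Iterative random-forest imputation of missing lab values (the
# Stekhoven-Buhlmann missForest loop), plus the complete-case subset used
# for sensitivity analysis. Only the ten labs are imputation targets; all
# other covariates serve as predictors.

imputation_predictors <- function() {
  c("age", "sex", "bmi", "charlson", "prior_systemic", "prior_radiation",
    "visceral_mets", "brain_mets", "lymph_node_mets", "n_bone_mets",
    "fracture_status", "ecog", "asa", "primary_tumor")
}

# Model frame for the forest learner: factors for categoricals, numerics
# elsewhere.
imputation_frame <- function(cohort) {
  df <- as.data.frame(cohort)[c(imputation_predictors(), pss_labs())]
  for (v in c("sex", "n_bone_mets", "fracture_status", "primary_tumor"))
    df[[v]] <- factor(df[[v]])
  for (v in c("charlson", "prior_systemic", "prior_radiation",
              "visceral_mets", "brain_mets", "lymph_node_mets"))
    df[[v]] <- as.numeric(df[[v]])
  df
}

#' Initialize missing labs with column means
#'
#' Standard starting point for the iterative imputation: each missing
#' continuous value is filled with the mean of the observed values in its
#' column. A column with no observed values at all is rejected by name.
#'
#' @param cohort A cohort table.
#' @return The cohort with labs mean-filled; the original missingness
#'   pattern is attached as attribute `"missing_cells"` (logical matrix).
#' @export
initialize_fill <- function(cohort) {
  mis <- matrix(vapply(pss_labs(), function(v) is.na(cohort[[v]]),
                       logical(nrow(cohort))),
                nrow = nrow(cohort),
                dimnames = list(NULL, pss_labs()))
  for (v in pss_labs()) {
    if (all(is.na(cohort[[v]])))
      stop(sprintf("column %s has no observed values", v), call. = FALSE)
    cohort[[v]][is.na(cohort[[v]])] <- mean(cohort[[v]], na.rm = TRUE)
  }
  attr(cohort, "missing_cells") <- mis
  cohort
}

#' Iterative random-forest (missForest-style) imputation
#'
#' Imputes missing lab values by the iterative scheme of the missForest
#' algorithm: starting from a mean fill, the labs with missing entries are
#' visited in ascending order of missingness (ties broken by column
#' position); for each, a random-forest regressor is fitted on the rows
#' where the lab was observed, using all other (currently completed)
#' variables as predictors, and the missing cells are re-predicted. The
#' loop stops when the normalized squared difference between successive
#' imputations first increases — returning the previous iteration's values
#' — or at `max_iter`.
#'
#' Originally observed values are never altered. Deterministic given
#' `seed` (forests run single-threaded with derived seeds).
#'
#' @param cohort A cohort table with (possibly) missing labs.
#' @param num_trees Trees per forest (default 100).
#' @param max_iter Maximum iterations (default 10).
#' @param seed Integer seed.
#' @param min_node_size Passed to [ranger::ranger()].
#' @return A `pss_imputation`: `cohort` (completed, provenance
#'   `"imputed"`), `iterations_run`, `oob_error` (per-variable out-of-bag
#'   MSE of the returned iteration's forests), and `trace` (the difference
#'   statistic per iteration).
#' @export
impute_missforest <- function(cohort, num_trees = 100, max_iter = 10,
                              seed = 1, min_node_size = 5) {
  labs <- pss_labs()
  n_mis <- vapply(labs, function(v) sum(is.na(cohort[[v]])), integer(1))
  targets <- labs[n_mis > 0]
  if (!length(targets)) {
    return(structure(list(cohort = cohort, iterations_run = 1L,
                          oob_error = setNames(numeric(0), character(0)),
                          trace = numeric(0)),
                     class = "pss_imputation"))
  }
  filled <- initialize_fill(cohort)
  mis <- attr(filled, "missing_cells")
  # ascending missingness, ties by column position
  targets <- targets[order(n_mis[targets])]
  df <- imputation_frame(filled)
  prev_df <- df
  prev_oob <- oob <- setNames(rep(NA_real_, length(targets)), targets)
  trace <- numeric(0)
  prev_diff <- Inf
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (vi in seq_along(targets)) {
      v <- targets[vi]
      obs <- !mis[, v]
      fit <- ranger::ranger(
        x = df[obs, setdiff(names(df), v), drop = FALSE],
        y = df[obs, v],
        num.trees = num_trees, min.node.size = min_node_size,
        seed = (seed + 97L * it + vi) %% .Machine$integer.max,
        num.threads = 1L)
      oob[v] <- fit$prediction.error
      pr <- predict(fit, data = df[mis[, v], setdiff(names(df), v),
                                   drop = FALSE],
                    num.threads = 1L)$predictions
      df[mis[, v], v] <- pr
    }
    diff_stat <- sum((df[targets] - prev_df[targets])^2) /
      sum(df[targets]^2)
    trace <- c(trace, diff_stat)
    if (diff_stat > prev_diff) {
      df <- prev_df      # divergence: keep the previous iteration
      oob <- prev_oob
      break
    }
    prev_df <- df
    prev_oob <- oob
    prev_diff <- diff_stat
  }
  out <- as.data.frame(cohort)
  for (v in targets) out[[v]][mis[, v]] <- df[[v]][mis[, v]]
  structure(list(cohort = as_pss_cohort(out, "imputed"),
                 iterations_run = iterations, oob_error = oob,
                 trace = trace),
            class = "pss_imputation")
}

#' @export
print.pss_imputation <- function(x, ...) {
  cat(sprintf("<pss_imputation> %d iteration(s); imputed labs: %s\n",
              x$iterations_run,
              if (length(x$oob_error)) paste(names(x$oob_error),
                                             collapse = ", ")
              else "none"))
  invisible(x)
}

#' Complete-case subset
#'
#' Patients with all ten labs observed, in the original order; the
#' substrate for the sensitivity analysis. An empty result warns rather
#' than fails.
#'
#' @param cohort A cohort table.
#' @return The subset cohort.
#' @export
complete_case_subset <- function(cohort) {
  keep <- stats::complete.cases(as.data.frame(cohort)[pss_labs()])
  if (!any(keep))
    warning("complete-case subset is empty", call. = FALSE)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
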