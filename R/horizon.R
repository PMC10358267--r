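#' Survival status at a fixed horizon
#'
#' Classifies each patient as `"DEAD"`, `"ALIVE"`, or `"UNKNOWN"` at a fixed
#' post-operative horizon. A patient is `DEAD` if death was observed at or
#' before the horizon, `ALIVE` if follow-up (or death) reached the horizon,
#' and `UNKNOWN` if censored alive before the horizon. A death recorded
#' exactly at the horizon counts as `DEAD`; censoring exactly at the horizon
#' counts as `ALIVE` (the patient was observed alive through the horizon).
#'
#' @param survival_months Non-negative numeric vector: observed time from
#'   index surgery to death or censoring, in months.
#' @param death_observed Logical vector: `TRUE` if the patient died at
#'   `survival_months`, `FALSE` if censored then.
#' @param horizon Single positive number of months, at most `admin_censor`.
#' @param admin_censor Administrative censoring time in months (default 24):
#'   follow-up beyond it is never used.
#' @return Character vector in `{"ALIVE","DEAD","UNKNOWN"}`.
#' @examples
#' horizon_status(c(2, 5, 2), c(TRUE, FALSE, FALSE), horizon = 3)
#' @export
horizon_status <- function(survival_months, death_observed, horizon,
                           admin_censor = 24) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("'horizon' must be a single positive number of months", call. = FALSE)
  if (horizon > admin_censor)
    stop(sprintf("horizon (%g) exceeds administrative censoring time (%g)",
                 horizon, admin_censor), call. = FALSE)
  if (any(survival_months < 0, na.rm = TRUE))
    stop("'survival_months' must be non-negative", call. = FALSE)
  death_observed <- as.logical(death_observed)
  status <- ifelse(death_observed & survival_months <= horizon, "DEAD",
                   ifelse(survival_months >= horizon, "ALIVE", "UNKNOWN"))
  status[is.na(survival_months) | is.na(death_observed)] <- NA_character_
  status
}

#' Horizon-status matrix for a cohort
#'
#' @param cohort A cohort table (see [read_cohort()]).
#' @param horizons Increasing vector of horizons in months.
#' @param admin_censor Administrative censoring time in months.
#' @return Character matrix, patients x horizons, with `patient_id` rownames
#'   and the horizons (months) as column names.
#' @export
status_matrix <- function(cohort, horizons, admin_censor = 24) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "survival_months", "death_observed") %in%
                  names(cohort)))
  if (is.unsorted(horizons, strictly = TRUE))
    stop("'horizons' must be strictly increasing", call. = FALSE)
  m <- vapply(horizons, function(h)
    horizon_status(cohort$survival_months, cohort$death_observed, h,
                   admin_censor),
    character(nrow(cohort)))
  m <- matrix(m, nrow = nrow(cohort),
              dimnames = list(cohort$patient_id, horizons))
  m
}

#' Ascertainment counts per horizon
#'
#' Number of patients whose status (dead or alive) is ascertainable at each
#' horizon, i.e. not `UNKNOWN`.
#'
#' @inheritParams status_matrix
#' @return Named integer vector over horizons.
#' @export
ascertainment_counts <- function(cohort, horizons, admin_censor = 24) {
  sm <- status_matrix(cohort, horizons, admin_censor)
  apply(sm, 2L, function(col) sum(col != "UNKNOWN", na.rm = TRUE))
}
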