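# Cohort table: column layout, validation, CSV reader/writer.

#' Names of the ten preoperative laboratory variables
#'
#' Column names used for the ten preoperative labs: sodium (`na`, mmol/L),
#' calcium (`ca`, mg/dL), albumin (`alb`, g/dL), alkaline phosphatase
#' (`alp`, U/L), blood urea nitrogen (`bun`, mg/dL), hemoglobin (`hgb`,
#' g/dL), absolute lymphocyte count (`alc`, 10^3/uL), absolute neutrophil
#' count (`anc`, 10^3/uL), white cell count (`wbc`, 10^3/uL), and platelets
#' (`plt`, 10^3/uL).
#'
#' @return Character vector of length 10.
#' @export
pss_labs <- function() {
  c("na", "ca", "alb", "alp", "bun", "hgb", "alc", "anc", "wbc", "plt")
}

cohort_boolean_cols <- function() {
  c("charlson", "prior_systemic", "prior_radiation", "visceral_mets",
    "brain_mets", "lymph_node_mets", "death_observed")
}

cohort_columns <- function() {
  c("patient_id", "age", "sex", "bmi", "charlson", "prior_systemic",
    "prior_radiation", "visceral_mets", "brain_mets", "lymph_node_mets",
    "n_bone_mets", "fracture_status", "ecog", "asa", "primary_tumor",
    pss_labs(), "survival_months", "death_observed")
}

#' Construct / validate a cohort table
#'
#' A cohort table is a `data.frame` with one row per patient: identifier,
#' demographics, tumor burden, functional status, the ten preoperative labs
#' (possibly missing), and — unless it is a covariate-only frame from
#' [sample_covariates()] — observed survival time in months plus a death
#' indicator. Invariants (unique ids, ECOG in 0–4, ASA in 1–5, non-negative
#' times and labs) are enforced here.
#'
#' @param df Data frame with the documented columns.
#' @param provenance One of `"real"`, `"synthetic"`, `"imputed"`.
#' @return The validated cohort, classed `pss_cohort`, with a
#'   `provenance` attribute.
#' @export
as_pss_cohort <- function(df, provenance = c("real", "synthetic", "imputed")) {
  provenance <- match.arg(provenance)
  validate_cohort(df)
  class(df) <- unique(c("pss_cohort", class(df)))
  attr(df, "provenance") <- provenance
  df
}

validate_cohort <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("cohort must be a non-empty data frame", call. = FALSE)
  need <- setdiff(cohort_columns(),
                  c("survival_months", "death_observed"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup))
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(!df$ecog %in% 0:4))
    stop("ecog must be an integer in 0..4", call. = FALSE)
  if (any(!df$asa %in% 1:5))
    stop("asa must be an integer in 1..5", call. = FALSE)
  for (v in pss_labs())
    if (any(df[[v]] < 0, na.rm = TRUE))
      stop(sprintf("lab '%s' has negative values", v), call. = FALSE)
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex))
    stop("sex must be 'female' or 'male' (row ",
         which(bad_sex)[1L], ")", call. = FALSE)
  if (any(!df$n_bone_mets %in% c("single", "multiple")))
    stop("n_bone_mets must be 'single' or 'multiple'", call. = FALSE)
  if (any(!df$fracture_status %in% c("impending", "complete")))
    stop("fracture_status must be 'impending' or 'complete'", call. = FALSE)
  if ("survival_months" %in% names(df)) {
    if (any(is.na(df$survival_months)) || any(df$survival_months < 0))
      stop("survival_months must be present and non-negative", call. = FALSE)
    if (!"death_observed" %in% names(df) || any(is.na(df$death_observed)))
      stop("death_observed must accompany survival_months", call. = FALSE)
  }
  invisible(df)
}

parse_numeric_col <- function(x, col) {
  x[x == ""] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop(sprintf("malformed numeric in column '%s', row %d: '%s'",
                 col, bad[1L], x[bad[1L]]), call. = FALSE)
  v
}

parse_boolean_col <- function(x, col) {
  x[x == ""] <- NA_character_
  v <- rep(NA, length(x))
  v[x %in% c("1", "TRUE", "true")] <- TRUE
  v[x %in% c("0", "FALSE", "false")] <- FALSE
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop(sprintf("malformed boolean in column '%s', row %d: '%s'",
                 col, bad[1L], x[bad[1L]]), call. = FALSE)
  v
}

#' Read a cohort table from CSV
#'
#' Expects the header documented in [as_pss_cohort()] / the README: booleans
#' coded 0/1, blank cells for missing labs. Unknown columns raise a warning
#' and are dropped; malformed numerics and duplicate patient ids fail with
#' the offending row/id.
#'
#' @param path Path to the CSV file.
#' @param provenance Provenance tag for the resulting table.
#' @return A `pss_cohort`.
#' @export
read_cohort <- function(path, provenance = "real") {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  extra <- setdiff(names(raw), cohort_columns())
  if (length(extra)) {
    warning("ignoring unknown cohort columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  miss <- setdiff(cohort_columns(), names(raw))
  if (length(miss))
    stop("cohort file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (v in c("age", "bmi", "ecog", "asa", pss_labs(), "survival_months"))
    df[[v]] <- parse_numeric_col(raw[[v]], v)
  for (v in cohort_boolean_cols())
    df[[v]] <- parse_boolean_col(raw[[v]], v)
  df$sex <- raw$sex
  df$n_bone_mets <- raw$n_bone_mets
  df$fracture_status <- raw$fracture_status
  df$primary_tumor <- raw$primary_tumor
  df <- df[cohort_columns()]
  as_pss_cohort(df, provenance)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: booleans become 0/1, missing labs become
#' blank cells. Reals round-trip to full double precision.
#'
#' @param cohort A `pss_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[cohort_columns()]
  for (v in cohort_boolean_cols())
    out[[v]] <- as.integer(out[[v]])
  for (v in c("age", "bmi", pss_labs(), "survival_months"))
    out[[v]] <- ifelse(is.na(out[[v]]), NA_character_,
                       formatC(out[[v]], digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
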