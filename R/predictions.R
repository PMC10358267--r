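# Prediction sets: per-model matrices of survival probabilities or integer
# scores over horizons, plus score->probability maps for score-only models.

#' Construct a prediction set
#'
#' One prediction set holds a single model's predictions: a patients x
#' horizons matrix of survival probabilities in `[0, 1]` (probability mode)
#' or integer scores (score mode). `NA` cells mark horizons a model does not
#' predict for a patient. Several published systems emit only an integer
#' score; such models support rank-based discrimination directly and the
#' probability-based metrics only through an explicit [score_map()].
#'
#' @param model Model name.
#' @param values Numeric matrix with `patient_id` rownames and horizon
#'   (months) column names; columns must be in strictly increasing horizon
#'   order.
#' @param mode `"probability"` or `"score"`.
#' @param score_map Optional [score_map()] for score-mode sets.
#' @return A `pss_predictions` object.
#' @export
prediction_set <- function(model, values,
                           mode = c("probability", "score"),
                           score_map = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop("'values' must be a matrix with patient_id rownames and horizon ",
         "column names", call. = FALSE)
  horizons <- as.numeric(colnames(values))
  if (anyNA(horizons) || is.unsorted(horizons, strictly = TRUE))
    stop("prediction horizons must be strictly increasing months",
         call. = FALSE)
  if (mode == "probability") {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "probability %g outside [0,1] for patient '%s' at %s months",
        values[bad[1L, 1L], bad[1L, 2L]],
        rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]),
        call. = FALSE)
  } else {
    if (any(values[!is.na(values)] != round(values[!is.na(values)])))
      stop("score-mode values must be integers", call. = FALSE)
  }
  structure(list(model = model, mode = mode, horizons = horizons,
                 values = values, score_map = score_map),
            class = "pss_predictions")
}

#' @export
print.pss_predictions <- function(x, ...) {
  cat(sprintf("<pss_predictions> model '%s' (%s mode): %d patients x %s\n",
              x$model, x$mode, nrow(x$values),
              paste(x$horizons, collapse = "/")),
      sep = "")
  invisible(x)
}

#' Does a prediction set support probability-based metrics?
#'
#' Probability-mode sets do; score-mode sets only when a score map is
#' attached. Mirrors the exclusion of score-only systems from calibration
#' and consistency analysis.
#'
#' @param pred A `pss_predictions`.
#' @return Logical scalar.
#' @export
has_probabilities <- function(pred) {
  pred$mode == "probability" || !is.null(pred$score_map)
}

#' Read long-format predictions from CSV
#'
#' Expects columns `patient_id, model, horizon_months, value` and optionally
#' `mode` (`probability`/`score`, constant within model; defaults to
#' probability). Returns one prediction set per model. Probabilities outside
#' `[0, 1]` fail with the offending cell; score-mode models without a map
#' are allowed but probability-based metrics are flagged unavailable
#' downstream.
#'
#' @param path Path to the CSV file.
#' @param score_maps Optional named list of [score_map()]s, keyed by model.
#' @return Named list of `pss_predictions`, one per model.
#' @export
read_predictions <- function(path, score_maps = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "model", "horizon_months", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"mode" %in% names(df)) df$mode <- "probability"
  out <- lapply(split(df, df$model), function(d) {
    mode <- unique(d$mode)
    if (length(mode) != 1L)
      stop(sprintf("model '%s' mixes prediction modes", d$model[1L]),
           call. = FALSE)
    if (mode == "probability") {
      bad <- which(d$value < 0 | d$value > 1)
      if (length(bad))
        stop(sprintf(
          "probability %g outside [0,1] for patient '%s', model '%s', %g months",
          d$value[bad[1L]], d$patient_id[bad[1L]], d$model[bad[1L]],
          d$horizon_months[bad[1L]]), call. = FALSE)
    }
    ids <- unique(d$patient_id)
    hs <- sort(unique(d$horizon_months))
    m <- matrix(NA_real_, length(ids), length(hs),
                dimnames = list(ids, hs))
    m[cbind(match(d$patient_id, ids), match(d$horizon_months, hs))] <- d$value
    prediction_set(d$model[1L], m, mode = mode,
                   score_map = score_maps[[d$model[1L]]])
  })
  out
}

#' Write prediction sets to long-format CSV
#'
#' @param preds A `pss_predictions` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  if (inherits(preds, "pss_predictions")) preds <- list(preds)
  rows <- lapply(preds, function(p) {
    idx <- which(!is.na(p$values), arr.ind = TRUE)
    data.frame(patient_id = rownames(p$values)[idx[, 1L]],
               model = p$model,
               horizon_months = p$horizons[idx[, 2L]],
               value = p$values[idx],
               mode = p$mode, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a score-to-probability map
#'
#' Maps a score-only model's integer scores to survival probabilities, per
#' horizon. `direction = "higher_better"` declares that a higher score means
#' better prognosis, in which case mapped probabilities must be
#' non-decreasing in score (non-increasing for `"lower_better"`).
#'
#' @param model Model name the map applies to.
#' @param horizons Named list: names are horizons in months, values are
#'   named numeric vectors `score -> survival probability`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return A `pss_score_map`.
#' @export
score_map <- function(model, horizons,
                      direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  for (h in names(horizons)) {
    v <- horizons[[h]]
    p <- unname(v[order(as.numeric(names(v)))])
    if (any(p < 0 | p > 1))
      stop("mapped probabilities must lie in [0,1]", call. = FALSE)
    mono <- if (direction == "higher_better") !is.unsorted(p)
            else !is.unsorted(rev(p))
    if (!mono)
      stop(sprintf(
        "score map for %s months is not monotone in the declared direction",
        h), call. = FALSE)
  }
  structure(list(model = model, direction = direction, horizons = horizons),
            class = "pss_score_map")
}

#' Read a score map from JSON
#'
#' JSON layout: `{"model": ..., "direction": ...,
#' "horizons": {"12": {"0": 0.9, "1": 0.6}}}`.
#'
#' @param path Path to the JSON file.
#' @return A `pss_score_map`.
#' @export
read_score_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  horizons <- lapply(j$horizons, function(h) unlist(h))
  score_map(j$model, horizons, direction = j$direction)
}

#' Convert a score-mode prediction set to probabilities
#'
#' Applies a [score_map()] horizon by horizon. Every observed score at every
#' mapped horizon must be covered; an unmapped score fails naming the score.
#'
#' @param pred A score-mode `pss_predictions`.
#' @param map A `pss_score_map` (defaults to the map attached to `pred`).
#' @return A probability-mode `pss_predictions`.
#' @export
apply_score_map <- function(pred, map = pred$score_map) {
  if (pred$mode != "score")
    stop("apply_score_map() expects a score-mode prediction set",
         call. = FALSE)
  if (is.null(map))
    stop("no score map supplied for model '", pred$model, "'", call. = FALSE)
  out <- pred$values
  for (j in seq_along(pred$horizons)) {
    h <- as.character(pred$horizons[j])
    lut <- map$horizons[[h]]
    if (is.null(lut))
      stop(sprintf("score map for model '%s' lacks horizon %s months",
                   pred$model, h), call. = FALSE)
    sc <- pred$values[, j]
    seen <- unique(sc[!is.na(sc)])
    missing_sc <- setdiff(seen, as.numeric(names(lut)))
    if (length(missing_sc))
      stop(sprintf("unmapped score %s", missing_sc[1L]), call. = FALSE)
    out[, j] <- unname(lut[as.character(sc)])
  }
  prediction_set(pred$model, out, mode = "probability")
}
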