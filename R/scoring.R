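# Scoring: transformed design, linear predictor, risk probability, triage
# category assignment.

# Build the n x 9 transformed design matrix in canonical coefficient order.
# Used both for scoring and for model revision.
build_design <- function(cohort, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  needed <- predictor_columns()
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing predictor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  na_counts <- vapply(cohort[needed], function(x) sum(is.na(x)), integer(1))
  if (any(na_counts > 0)) {
    bad <- names(na_counts)[na_counts > 0]
    ids <- if ("id" %in% names(cohort)) {
      first <- which(rowSums(is.na(cohort[needed])) > 0)[1]
      sprintf(" (first affected record id: %s)", cohort$id[first])
    } else ""
    abort(paste0("Missing predictor value(s) in column(s): ",
                 paste(bad, collapse = ", "), ids,
                 ". Run impute_missing() before scoring."))
  }
  cbind(
    age = transform_age(cohort$age_months, coeffs$age_transform),
    heart_rate = cohort$heart_rate,
    temperature = cohort$temperature_c,
    muac = cohort$muac_mm,
    transformed_spo2 = transform_spo2(cohort$spo2, coeffs$spo2_transform),
    parent_concern = cohort$parent_concern,
    difficulty_breathing = cohort$difficulty_breathing,
    oedema = cohort$oedema,
    pallor = cohort$pallor
  )
}

#' Linear predictor and risk for a single record
#'
#' Computes `logit(p) = intercept + sum(coefficient * transformed predictor)`
#' for one patient record and converts it to a probability with a
#' numerically stable inverse logit (extreme logits return exactly 0 or 1).
#'
#' @param record A one-row data frame with the canonical predictor columns
#'   (`age_months`, `heart_rate`, `temperature_c`, `muac_mm`, `spo2`,
#'   `parent_concern`, `difficulty_breathing`, `oedema`, `pallor`).
#' @param coeffs A [coefficient_set()].
#' @return A list with elements `linear_predictor` and `probability`.
#' @export
linear_predictor <- function(record, coeffs) {
  record <- tibble::as_tibble(record)
  if (nrow(record) != 1L) abort("`record` must be a single row; use predict_risk() for cohorts.")
  X <- build_design(record, coeffs)
  lp <- drop(coeffs$intercept + X %*% coeffs$coefficients)
  list(linear_predictor = unname(lp), probability = unname(inv_logit(lp)))
}

#' Score a cohort with a triage model
#'
#' Vectorized scoring: adds `linear_predictor` and `probability` columns to
#' the cohort, preserving row order. All nine predictors must be non-missing
#' (run [impute_missing()] first).
#'
#' @param cohort A cohort data frame.
#' @param coeffs A [coefficient_set()].
#' @return The cohort as a tibble with `linear_predictor` and `probability`
#'   columns added.
#' @export
predict_risk <- function(cohort, coeffs) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0L) abort("Cohort is empty.")
  X <- build_design(cohort, coeffs)
  lp <- drop(coeffs$intercept + X %*% coeffs$coefficients)
  dplyr::mutate(cohort,
                linear_predictor = as.numeric(lp),
                probability = inv_logit(as.numeric(lp)))
}

#' Risk-threshold pair for triage stratification
#'
#' @param low,high Probability thresholds in (0,1) with `low < high`. Risks
#'   at or below `low` are non-urgent; above `high`, emergency.
#' @param provenance How the thresholds were chosen (free text).
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(low, high, provenance = "user-supplied") {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 || length(high) != 1 ||
      low <= 0 || high >= 1 || !(low < high)) {
    abort("Thresholds must satisfy 0 < low < high < 1.")
  }
  structure(list(low = low, high = high, provenance = provenance),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair: low <= %.4g < priority <= %.4g < emergency (%s)>\n",
              x$low, x$high, x$provenance))
  invisible(x)
}

#' Triage category labels, in increasing order of urgency
#' @return `c("non_urgent", "priority", "emergency")`
#' @export
triage_levels <- function() c("non_urgent", "priority", "emergency")

#' Assign triage categories from risk probabilities
#'
#' Boundaries are inclusive on the left: `p <= low` is non-urgent,
#' `low < p <= high` is priority, and `p > high` is emergency.
#'
#' @param probability Numeric vector of risk probabilities in \[0, 1\].
#' @param thresholds A [threshold_pair()].
#' @return A factor with levels [triage_levels()].
#' @export
categorize <- function(probability, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  assert_prob_vector(probability, "probability")
  out <- dplyr::case_when(
    probability <= thresholds$low ~ "non_urgent",
    probability <= thresholds$high ~ "priority",
    TRUE ~ "emergency"
  )
  factor(out, levels = triage_levels())
}
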