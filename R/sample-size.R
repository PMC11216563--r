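# Sample-size calculators used to plan validation cohorts.

#' Events-rule minimum sample size
#'
#' The simple events-per-variable rule `N = (n * 10) / I`, where `n` is the
#' number of candidate predictors and `I` the anticipated event rate; the
#' result is rounded up. With nine predictors and a 20% event rate this gives
#' 450 participants.
#'
#' @param n_predictors Number of candidate predictor variables.
#' @param event_rate Anticipated event rate in (0, 1\].
#' @return Minimum sample size (integer).
#' @export
events_rule_sample_size <- function(n_predictors, event_rate) {
  if (n_predictors < 1 || n_predictors != round(n_predictors)) {
    abort("`n_predictors` must be a positive integer.")
  }
  if (event_rate <= 0 || event_rate > 1) {
    abort("`event_rate` must be in (0, 1].")
  }
  as.integer(ceiling(n_predictors * 10 / event_rate))
}

#' Minimum sample size for validating a binary-outcome risk model
#'
#' The four-criterion procedure of Riley et al. for prediction models with a
#' binary outcome, given an anticipated Cox-Snell R-squared, outcome
#' prevalence and number of candidate predictors:
#'
#' 1. **Global shrinkage**: expected uniform shrinkage at least `shrinkage`
#'    (default 0.90): `n = P / ((S - 1) * ln(1 - R2_CS / S))`.
#' 2. **Small apparent-vs-adjusted R2 difference**: at most
#'    `max_r2_difference` absolute optimism in R2_CS; solves for the
#'    shrinkage `S = R2 / (R2 + d * max(R2_CS))` implied by that optimism
#'    and applies the criterion-1 formula, where the maximum possible
#'    Cox-Snell R2 at prevalence phi is
#'    `1 - exp(2 * (phi*ln(phi) + (1-phi)*ln(1-phi)))`.
#' 3. **Precise overall risk (intercept)**: margin of error
#'    `intercept_margin` for the outcome prevalence:
#'    `n = (1.96 / margin)^2 * phi * (1 - phi)`.
#' 4. **Events per candidate predictor**: at least `events_per_predictor`
#'    events per predictor: `n = P * EPP / phi`.
#'
#' The overall requirement is the maximum across criteria. An optional
#' C-statistic is recorded as provenance (the Cox-Snell R-squared must be
#' supplied directly).
#'
#' @param n_predictors Number of candidate predictor parameters `P`.
#' @param prevalence Outcome prevalence `phi` in (0, 1).
#' @param r2_cs Anticipated Cox-Snell R-squared; must be below its
#'   theoretical maximum at `prevalence`.
#' @param max_r2_difference Acceptable apparent-vs-adjusted R2 difference
#'   (default 0.05).
#' @param intercept_margin Margin of error for the intercept / overall risk
#'   (default 0.05).
#' @param events_per_predictor Required events per predictor (default 7).
#' @param shrinkage Target global shrinkage factor (default 0.9).
#' @param c_statistic Optional C-statistic, recorded for provenance.
#' @return A tibble with one row per criterion (`criterion`, `n`) plus an
#'   `overall` attribute; the overall minimum is also the `n` of the row
#'   with `criterion == "overall"`.
#' @export
riley_min_sample_size <- function(n_predictors,
                                  prevalence,
                                  r2_cs,
                                  max_r2_difference = 0.05,
                                  intercept_margin = 0.05,
                                  events_per_predictor = 7,
                                  shrinkage = 0.9,
                                  c_statistic = NULL) {
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1).")
  if (max_r2_difference <= 0) abort("`max_r2_difference` must be positive.")
  if (intercept_margin <= 0) abort("`intercept_margin` must be positive.")
  if (events_per_predictor <= 0) abort("`events_per_predictor` must be positive.")
  if (shrinkage <= 0 || shrinkage >= 1) abort("`shrinkage` must be in (0, 1).")
  phi <- prevalence
  # Max Cox-Snell R2 at this prevalence: 1 - exp(2/n * lnL0), lnL0 evaluated
  # per observation for the null (prevalence-only) model.
  max_r2 <- 1 - exp(2 * (phi * log(phi) + (1 - phi) * log(1 - phi)))
  if (r2_cs <= 0 || r2_cs >= max_r2) {
    abort(sprintf(
      "`r2_cs` must be in (0, %.4f), the maximum Cox-Snell R2 at prevalence %.3g.",
      max_r2, phi))
  }
  P <- n_predictors

  shrink_n <- function(S) P / ((S - 1) * log(1 - r2_cs / S))
  # Criterion 1: global shrinkage >= target.
  n1 <- shrink_n(shrinkage)
  # Criterion 2: optimism in apparent R2 at most `max_r2_difference`.
  s2 <- r2_cs / (r2_cs + max_r2_difference * max_r2)
  n2 <- shrink_n(s2)
  # Criterion 3: precise estimate of the overall risk (model intercept).
  n3 <- (qnorm(0.975) / intercept_margin)^2 * phi * (1 - phi)
  # Criterion 4: events per candidate predictor.
  n4 <- P * events_per_predictor / phi

  ns <- pmax(1, ceiling(c(n1, n2, n3, n4)))
  out <- tibble::tibble(
    criterion = c("global_shrinkage", "r2_difference", "intercept_precision",
                  "events_per_predictor", "overall"),
    n = as.integer(c(ns, max(ns)))
  )
  attr(out, "inputs") <- list(
    n_predictors = P, prevalence = phi, r2_cs = r2_cs, max_r2_cs = max_r2,
    max_r2_difference = max_r2_difference, intercept_margin = intercept_margin,
    events_per_predictor = events_per_predictor, shrinkage = shrinkage,
    c_statistic = c_statistic
  )
  attr(out, "overall") <- max(ns)
  out
}
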