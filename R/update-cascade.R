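# The three-step model-updating cascade: recalibration-in-the-large ->
# logistic recalibration -> full model revision.

#' Recalibration-in-the-large
#'
#' Re-estimates only the model intercept on the validation data, keeping the
#' original linear predictor as a fixed offset: addresses a difference in
#' baseline risk between development and validation populations. By the
#' maximum-likelihood score equation, the updated predictions have mean equal
#' to the observed event rate (E:O = 1 on the fitting data).
#'
#' @param lp Baseline linear predictors (logit scale).
#' @param outcomes 0/1 outcomes.
#' @return A list: `alpha` (the intercept update), `fit` (the
#'   [fit_logistic()] result), and `lp_updated = alpha + lp`.
#' @export
recalibrate_in_the_large <- function(lp, outcomes) {
  assert_binary_vector(outcomes)
  assert_same_length(lp, outcomes, "lp")
  fit <- fit_logistic(x = NULL, y = outcomes, offset = lp)
  alpha <- unname(fit$coefficients["(Intercept)"])
  list(alpha = alpha, fit = fit, lp_updated = alpha + lp)
}

#' Logistic recalibration
#'
#' Re-estimates the intercept and a single slope on the original linear
#' predictor: `logit(p_new) = alpha + beta * lp`. With a positive slope this
#' is a strictly increasing transform of the score, so discrimination (AUROC)
#' is unchanged; calibration intercept and slope reach their ideal values of
#' 0 and 1 on the fitting data.
#'
#' @inheritParams recalibrate_in_the_large
#' @return A list: `alpha`, `beta`, `fit`, and `lp_updated = alpha + beta*lp`.
#' @export
logistic_recalibration <- function(lp, outcomes) {
  assert_binary_vector(outcomes)
  assert_same_length(lp, outcomes, "lp")
  fit <- fit_logistic(x = matrix(lp, ncol = 1, dimnames = list(NULL, "lp")),
                      y = outcomes)
  alpha <- unname(fit$coefficients["(Intercept)"])
  beta <- unname(fit$coefficients["lp"])
  list(alpha = alpha, beta = beta, fit = fit,
       lp_updated = alpha + beta * lp)
}

#' Full model revision
#'
#' Re-estimates the intercept and all nine predictor coefficients on the
#' validation cohort, keeping the predictor set and the transforms declared
#' by the template coefficient set. Non-convergence or suspected separation
#' is surfaced via warnings and the returned fit flags.
#'
#' @param cohort An imputed cohort tibble (no missing predictors) with an
#'   `endpoint` column (see [derive_composite_endpoint()]).
#' @param template A [coefficient_set()] declaring predictor names and
#'   transforms; its coefficient values are not used.
#' @param outcomes Optional 0/1 vector overriding `cohort$endpoint`.
#' @return A [coefficient_set()] with the refitted coefficients; the
#'   underlying [fit_logistic()] result is attached as attribute `"fit"`.
#' @export
revise_model <- function(cohort, template, outcomes = NULL) {
  stopifnot(inherits(template, "coefficient_set"))
  y <- outcomes %||% cohort$endpoint
  if (is.null(y)) {
    abort("Cohort has no `endpoint` column; run derive_composite_endpoint().")
  }
  X <- build_design(cohort, template)
  fit <- fit_logistic(x = X, y = y)
  out <- coefficient_set(
    intercept = unname(fit$coefficients["(Intercept)"]),
    coefficients = fit$coefficients[predictor_names()],
    age_transform = template$age_transform,
    spo2_transform = template$spo2_transform,
    muac_unit = template$muac_unit,
    label = sprintf("revision of '%s' (n=%d)", template$label, fit$n)
  )
  attr(out, "fit") <- fit
  out
}

#' Run the three-step update cascade
#'
#' Scores the cohort with the base model, then applies, in order,
#' recalibration-in-the-large, logistic recalibration, and full revision —
#' assessing discrimination (AUROC), calibration (E:O, CITL, intercept,
#' slope, reliability curve) and the Brier score at baseline and after each
#' step on the same cohort. In-sample log-likelihood is non-decreasing across
#' the stages because each stage's score family nests the previous one
#' (the revision template defaults to the base model's transforms, which
#' preserves the nesting).
#'
#' @param cohort Imputed cohort tibble with an `endpoint` column.
#' @param base The baseline [coefficient_set()] to update.
#' @param template Revision template; defaults to `base`.
#' @param n_bins Reliability-curve bins per stage.
#' @return An object of class `update_cascade`: per-stage metrics tibble
#'   (`stages`), per-stage calibration curves (`curves`), the per-stage score
#'   vectors (`scores`), the revised model (`revised`), and the stage fits.
#' @export
run_update_cascade <- function(cohort, base, template = base, n_bins = 10L) {
  stopifnot(inherits(base, "coefficient_set"))
  if (!"endpoint" %in% names(cohort)) {
    abort("Cohort has no `endpoint` column; run derive_composite_endpoint().")
  }
  y <- cohort$endpoint
  scored <- predict_risk(cohort, base)
  lp0 <- scored$linear_predictor

  recal <- recalibrate_in_the_large(lp0, y)
  logrec <- logistic_recalibration(lp0, y)
  revised <- revise_model(cohort, template)
  rev_fit <- attr(revised, "fit")
  lp3 <- predict_risk(cohort, revised)$linear_predictor

  lps <- list(baseline = lp0, recal_large = recal$lp_updated,
              logistic_recal = logrec$lp_updated, revision = lp3)
  loglik <- function(lp) {
    mu <- clamp_prob(inv_logit(lp))
    sum(y * log(mu) + (1 - y) * log1p(-mu))
  }
  stage_rows <- list()
  curves <- list()
  scores <- list()
  for (stage in names(lps)) {
    p <- inv_logit(lps[[stage]])
    scores[[stage]] <- p
    disc <- auroc(p, y)
    cal <- calibration_assessment(p, y, n_bins = n_bins)
    stage_rows[[stage]] <- tibble::tibble(
      stage = stage,
      auroc = disc$auroc, auroc_low = disc$ci_low, auroc_high = disc$ci_high,
      brier = brier_score(p, y),
      eo_ratio = cal$eo_ratio, citl = cal$citl,
      cal_intercept = cal$cal_intercept, cal_slope = cal$cal_slope,
      log_likelihood = loglik(lps[[stage]])
    )
    curves[[stage]] <- dplyr::mutate(cal$curve, stage = stage, .before = 1)
  }
  structure(
    list(
      stages = dplyr::bind_rows(stage_rows),
      curves = dplyr::bind_rows(curves) |>
        dplyr::mutate(stage = factor(.data$stage, levels = names(lps))),
      scores = scores,
      alpha_recal = recal$alpha,
      recal_coeffs = c(alpha = logrec$alpha, beta = logrec$beta),
      revised = revised,
      fits = list(recal_large = recal$fit, logistic_recal = logrec$fit,
                  revision = rev_fit),
      n = length(y)
    ),
    class = "update_cascade"
  )
}

#' @export
print.update_cascade <- function(x, ...) {
  cat(sprintf("<update_cascade: n=%d>\n", x$n))
  print(as.data.frame(dplyr::mutate(x$stages, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 4)))), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method
tidy.update_cascade <- function(x, ...) x$stages

#' @exportS3Method
glance.update_cascade <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    auroc_baseline = x$stages$auroc[1],
    auroc_revision = x$stages$auroc[4],
    cal_slope_baseline = x$stages$cal_slope[1],
    alpha_recal = x$alpha_recal,
    beta_recal = unname(x$recal_coeffs["beta"])
  )
}

#' @exportS3Method
autoplot.update_cascade <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed event rate",
                  title = "Calibration across update stages")
}
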