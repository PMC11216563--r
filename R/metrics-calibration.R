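#' Calibration assessment of predicted risks
#'
#' Computes the standard calibration summaries of a risk model on a
#' validation sample:
#'
#' * **E:O ratio** — mean predicted risk over observed event rate (1 is
#'   ideal; above 1 means overprediction).
#' * **Calibration-in-the-large (CITL)** — intercept of a logistic fit of the
#'   outcome on `logit(score)` with the slope fixed at 1 (offset model);
#'   0 is ideal.
#' * **Calibration intercept and slope** — from the unconstrained logistic
#'   fit of the outcome on `logit(score)`; ideal is intercept 0, slope 1
#'   (slopes below 1 indicate predictions that are too extreme).
#' * **Reliability curve** — mean predicted vs observed event rate in
#'   equal-count quantile bins (default 10), for calibration plots.
#'
#' Scores exactly 0 or 1 are clamped to `[1e-8, 1 - 1e-8]` before the
#' logit-based fits.
#'
#' @param scores Predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param n_bins Number of equal-count bins for the reliability curve.
#' @return An object of class `calibration_result` with fields `eo_ratio`,
#'   `citl`, `cal_intercept`, `cal_slope`, `curve` (tibble: `bin`,
#'   `mean_predicted`, `observed_rate`, `n`) and the two underlying fits.
#' @export
calibration_assessment <- function(scores, outcomes, n_bins = 10L) {
  assert_prob_vector(scores)
  assert_binary_vector(outcomes)
  assert_same_length(scores, outcomes)
  if (all(outcomes == 0) || all(outcomes == 1)) {
    abort("Calibration needs both outcome classes present.")
  }
  lp <- logit(clamp_prob(scores))
  fit_citl <- fit_logistic(x = NULL, y = outcomes, offset = lp)
  # slope fit is undefined for constant scores or n <= 2; report NA then
  fit_slope <- tryCatch(
    fit_logistic(x = matrix(lp, ncol = 1,
                            dimnames = list(NULL, "logit_score")),
                 y = outcomes),
    error = function(e) {
      warn(paste0("Calibration slope not estimable: ", conditionMessage(e)))
      NULL
    }
  )
  structure(
    list(
      eo_ratio = mean(scores) / mean(outcomes),
      citl = unname(fit_citl$coefficients["(Intercept)"]),
      cal_intercept = if (is.null(fit_slope)) NA_real_ else
        unname(fit_slope$coefficients["(Intercept)"]),
      cal_slope = if (is.null(fit_slope)) NA_real_ else
        unname(fit_slope$coefficients["logit_score"]),
      curve = reliability_curve(scores, outcomes, n_bins),
      n = length(scores),
      citl_fit = fit_citl,
      slope_fit = fit_slope
    ),
    class = "calibration_result"
  )
}

# Equal-count quantile bins; ties broken by stable order on (score, index).
reliability_curve <- function(scores, outcomes, n_bins) {
  n <- length(scores)
  n_bins <- max(1L, min(as.integer(n_bins), n))
  ord <- order(scores, seq_along(scores))
  bin <- ceiling(seq_len(n) * n_bins / n)  # sizes differ by at most 1
  tibble::tibble(score = scores[ord], outcome = outcomes[ord], bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_predicted = mean(.data$score),
      observed_rate = mean(.data$outcome),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration (n=%d): E:O %.3f | CITL %.4f | intercept %.4f | slope %.4f\n",
    x$n, x$eo_ratio, x$citl, x$cal_intercept, x$cal_slope))
  invisible(x)
}

#' @exportS3Method
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(
    eo_ratio = x$eo_ratio, citl = x$citl,
    cal_intercept = x$cal_intercept, cal_slope = x$cal_slope, n = x$n
  )
}

#' @exportS3Method
autoplot.calibration_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$mean_predicted, y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean predicted risk", y = "Observed event rate", size = "Bin n",
      title = sprintf("Calibration: slope %.2f, CITL %.3f, E:O %.2f",
                      object$cal_slope, object$citl, object$eo_ratio)
    )
}
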