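#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; ranges 0 (perfect) to 1.
#'
#' @param scores Predicted probabilities in \[0, 1\].
#' @param outcomes 0/1 outcomes of equal length.
#' @return A single number in \[0, 1\].
#' @export
brier_score <- function(scores, outcomes) {
  assert_prob_vector(scores)
  assert_binary_vector(outcomes)
  assert_same_length(scores, outcomes)
  if (length(scores) < 1) abort("Need at least one observation.")
  mean((scores - outcomes)^2)
}

#' Area under the ROC curve with confidence interval
#'
#' AUROC via the rank (Mann-Whitney) formulation with ties counted one half:
#' the probability that a randomly chosen case scores above a randomly chosen
#' non-case. The default confidence interval is the DeLong analytic interval
#' (midrank formulation); a seeded percentile bootstrap is available.
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param outcomes 0/1 outcomes.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param B Bootstrap replicates (bootstrap CI only).
#' @param seed Seed for the bootstrap CI.
#' @return An object of class `discrimination_result`: `auroc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `se`, `ci_method` and `roc_points`
#'   (a tibble of (fpr, tpr) from (0,0) to (1,1)).
#' @export
auroc <- function(scores, outcomes, ci_method = c("delong", "bootstrap"),
                  conf_level = 0.95, B = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (!is.numeric(scores) || anyNA(scores)) abort("`scores` must be numeric, no NA.")
  assert_binary_vector(outcomes)
  assert_same_length(scores, outcomes)
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUROC needs at least one positive and one negative outcome.")
  }
  auc <- auc_rank(scores, outcomes)

  if (ci_method == "delong") {
    se <- delong_se(scores, outcomes)
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- c(auc - z * se, auc + z * se)
  } else {
    set.seed(seed)
    idx_pos <- which(outcomes == 1)
    idx_neg <- which(outcomes == 0)
    reps <- vapply(seq_len(B), function(b) {
      i <- c(sample(idx_pos, n_pos, replace = TRUE),
             sample(idx_neg, n_neg, replace = TRUE))
      auc_rank(scores[i], outcomes[i])
    }, numeric(1))
    se <- stats::sd(reps)
    ci <- unname(quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
  }
  structure(
    list(
      auroc = auc,
      ci_low = max(0, min(ci[1], auc)),
      ci_high = min(1, max(ci[2], auc)),
      se = se,
      conf_level = conf_level,
      ci_method = ci_method,
      n_pos = n_pos,
      n_neg = n_neg,
      roc_points = roc_points(scores, outcomes)
    ),
    class = "discrimination_result"
  )
}

# Rank/Mann-Whitney AUROC, ties counted 1/2.
auc_rank <- function(scores, outcomes) {
  r <- rank(scores, ties.method = "average")
  m <- sum(outcomes == 1)
  n <- sum(outcomes == 0)
  (sum(r[outcomes == 1]) - m * (m + 1) / 2) / (m * n)
}

# DeLong standard error via the midrank formulation (Sun & Xu).
delong_se <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

# ROC curve points, monotone from (0,0) to (1,1).
roc_points <- function(scores, outcomes) {
  ord <- order(scores, decreasing = TRUE)
  y <- outcomes[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # one point per unique threshold
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(1 - y) / sum(1 - y)
  tibble::tibble(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%d%% CI %.3f-%.3f, %s; %d cases / %d non-cases)\n",
              x$auroc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method
tidy.discrimination_result <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
    ci_method = x$ci_method, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @exportS3Method
autoplot.discrimination_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve: AUROC %.3f (%.3f-%.3f)",
                      object$auroc, object$ci_low, object$ci_high)
    ) +
    ggplot2::coord_equal()
}
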