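#' Risk-stratification table
#'
#' Counts patients and composite endpoints per triage category
#' (non-urgent / priority / emergency) under a pair of risk thresholds —
#' the object from which the classification-accuracy metrics are computed.
#'
#' @param scores Predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param thresholds A [threshold_pair()].
#' @return A tibble of class `stratification_table` with columns `category`,
#'   `n_total`, `n_endpoint`; the thresholds are attached as attribute
#'   `"thresholds"`.
#' @export
stratification_table <- function(scores, outcomes, thresholds) {
  assert_prob_vector(scores)
  assert_binary_vector(outcomes)
  assert_same_length(scores, outcomes)
  cat3 <- categorize(scores, thresholds)
  out <- tibble::tibble(category = factor(triage_levels(), levels = triage_levels())) |>
    dplyr::left_join(
      tibble::tibble(category = cat3, outcome = outcomes) |>
        dplyr::group_by(.data$category, .drop = FALSE) |>
        dplyr::summarise(n_total = dplyr::n(),
                         n_endpoint = sum(.data$outcome), .groups = "drop"),
      by = "category"
    ) |>
    dplyr::mutate(n_total = dplyr::coalesce(.data$n_total, 0L),
                  n_endpoint = dplyr::coalesce(as.integer(.data$n_endpoint), 0L))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("stratification_table", class(out))
  out
}

#' Build a stratification table directly from category counts
#'
#' Used to analyse published classification tables when only the per-category
#' totals and endpoint counts are available.
#'
#' @param n_total Totals for (non_urgent, priority, emergency).
#' @param n_endpoint Endpoint counts for the same categories.
#' @param thresholds The [threshold_pair()] the counts were produced with.
#' @return A `stratification_table` tibble.
#' @export
stratification_table_from_counts <- function(n_total, n_endpoint, thresholds) {
  stopifnot(length(n_total) == 3, length(n_endpoint) == 3)
  if (any(n_endpoint > n_total)) abort("`n_endpoint` cannot exceed `n_total`.")
  out <- tibble::tibble(
    category = factor(triage_levels(), levels = triage_levels()),
    n_total = as.integer(n_total),
    n_endpoint = as.integer(n_endpoint)
  )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("stratification_table", class(out))
  out
}

#' Classification metrics of a stratification table
#'
#' For each boundary of the three-category table the patients above the
#' boundary are the test-positives:
#'
#' * `non_urgent` row (low boundary): positive = priority or emergency;
#' * `priority` row: the middle-category diagnostic, reported under the
#'   documented convention positive = priority-or-emergency vs non-urgent
#'   (identical 2x2 to the low boundary; published middle columns are not
#'   arithmetically reconstructible from category counts);
#' * `emergency` row (high boundary): positive = emergency alone.
#'
#' Sensitivity, specificity, NPV and PPV carry Wilson score intervals;
#' likelihood ratios carry Katz log-method intervals. All metrics are
#' computed from raw counts, never from rounded intermediates; a zero
#' denominator yields `NA` rather than 0.
#'
#' @param table A [stratification_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per boundary: counts (`tp`, `fp`, `tn`,
#'   `fn`) and estimate/lower/upper columns for each metric.
#' @export
table_metrics <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "stratification_table"))
  tot <- table$n_total
  ev <- table$n_endpoint
  E <- sum(ev)
  NN <- sum(tot)
  if (E == 0 || E == NN) {
    abort("Table is degenerate: need both endpoint and non-endpoint patients.")
  }
  two_by_two <- function(pos_idx) {
    tp <- sum(ev[pos_idx])
    fp <- sum(tot[pos_idx]) - tp
    fn <- E - tp
    tn <- (NN - E) - fp
    c(tp = tp, fp = fp, tn = tn, fn = fn)
  }
  rows <- list(
    non_urgent = two_by_two(2:3),
    priority = two_by_two(2:3),  # documented middle-column convention
    emergency = two_by_two(3)
  )
  purrr::imap_dfr(rows, function(ct, boundary) {
    tp <- ct["tp"]; fp <- ct["fp"]; tn <- ct["tn"]; fn <- ct["fn"]
    sens <- prop_ci(tp, tp + fn, conf_level)
    spec <- prop_ci(tn, tn + fp, conf_level)
    ppv_ci <- prop_ci(tp, tp + fp, conf_level)
    npv_ci <- prop_ci(tn, tn + fn, conf_level)
    lrp <- lr_ci(tp, fn, fp, tn, positive = TRUE, conf_level)
    lrn <- lr_ci(tp, fn, fp, tn, positive = FALSE, conf_level)
    tibble::tibble(
      boundary = boundary,
      tp = unname(tp), fp = unname(fp), tn = unname(tn), fn = unname(fn),
      sensitivity = sens[1], sensitivity_low = sens[2], sensitivity_high = sens[3],
      specificity = spec[1], specificity_low = spec[2], specificity_high = spec[3],
      ppv = ppv_ci[1], ppv_low = ppv_ci[2], ppv_high = ppv_ci[3],
      npv = npv_ci[1], npv_low = npv_ci[2], npv_high = npv_ci[3],
      lr_pos = lrp[1], lr_pos_low = lrp[2], lr_pos_high = lrp[3],
      lr_neg = lrn[1], lr_neg_low = lrn[2], lr_neg_high = lrn[3]
    )
  })
}

# Wilson score interval; point estimate is x/n. Returns (est, low, high).
prop_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  x <- unname(x); n <- unname(n)
  p <- x / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(p, max(0, centre - half), min(1, centre + half))
}

# Katz log-method CI for likelihood ratios. Undefined pieces -> NA.
lr_ci <- function(tp, fn, fp, tn, positive, conf_level = 0.95) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (positive) {
    if (1 - spec == 0 || tp + fn == 0) return(c(NA_real_, NA_real_, NA_real_))
    est <- sens / (1 - spec)
    if (tp == 0 || fp == 0) return(c(est, NA_real_, NA_real_))
    se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  } else {
    if (spec == 0 || tp + fn == 0) return(c(NA_real_, NA_real_, NA_real_))
    est <- (1 - sens) / spec
    if (fn == 0 || tn == 0) return(c(est, NA_real_, NA_real_))
    se <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  }
  unname(c(est, est * exp(-z * se), est * exp(z * se)))
}

#' Select risk thresholds from target sensitivity and specificity
#'
#' The low-risk threshold is chosen at the target sensitivity (default 90%),
#' limiting endpoint cases misclassified as non-urgent; the high-risk
#' threshold at the target specificity (default 90%), limiting non-cases
#' classified as emergency. Candidates are the observed score values plus 0/1
#' sentinels; "positive" means score strictly above the threshold. The low
#' threshold is the largest candidate below the high threshold whose
#' sensitivity meets the target; the high threshold is the smallest candidate
#' whose specificity meets the target.
#'
#' @param scores Predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param sens_target,spec_target Targets in \[0, 1\].
#' @return A [threshold_pair()] whose provenance records the targets and the
#'   sensitivity/specificity achieved at the chosen thresholds.
#' @export
select_thresholds <- function(scores, outcomes,
                              sens_target = 0.90, spec_target = 0.90) {
  assert_prob_vector(scores)
  assert_binary_vector(outcomes)
  assert_same_length(scores, outcomes)
  if (all(outcomes == 0) || all(outcomes == 1)) {
    abort("Threshold selection needs both outcome classes.")
  }
  cand <- sort(unique(c(0, scores, 1)))
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  sens_at <- vapply(cand, function(t) mean(pos > t), numeric(1))
  spec_at <- vapply(cand, function(t) mean(neg <= t), numeric(1))

  ok_spec <- spec_at >= spec_target
  if (!any(ok_spec)) {
    abort(sprintf(
      "Specificity target %.2f unattainable; maximum achievable is %.3f.",
      spec_target, max(spec_at)))
  }
  ok_sens <- sens_at >= sens_target
  if (!any(ok_sens)) {
    abort(sprintf(
      "Sensitivity target %.2f unattainable; maximum achievable is %.3f.",
      sens_target, max(sens_at)))
  }
  low <- max(cand[ok_sens])
  high <- min(cand[ok_spec])
  if (!(low < high)) {
    # Crossing: specificity is non-decreasing in the threshold, so first try
    # raising `high` above `low`; otherwise lower `low` below `high`.
    raise <- ok_spec & cand > low & cand < 1
    lower <- ok_sens & cand < high
    if (any(raise)) {
      high <- min(cand[raise])
    } else if (any(lower)) {
      low <- max(cand[lower])
    } else {
      abort(sprintf(paste0(
        "Thresholds cross: sensitivity target met only up to %.4g but ",
        "specificity target first met at %.4g; achievable frontier: ",
        "sens %.3f / spec %.3f at that point."),
        low, high, sens_at[cand == high][1], spec_at[cand == high][1]))
    }
  }
  low <- max(low, .Machine$double.eps)
  high <- min(high, 1 - .Machine$double.eps)
  threshold_pair(
    low, high,
    provenance = sprintf(
      "selected: sens>=%.2f at low (achieved %.3f), spec>=%.2f at high (achieved %.3f)",
      sens_target, sens_at[cand == low][1] %||% NA_real_,
      spec_target, spec_at[cand == high][1] %||% NA_real_)
  )
}
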