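test_that("Brier score matches hand arithmetic and its bounds", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 4), c(0, 1, 1, 0)), 0.25)
  expect_equal(brier_score(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(brier_score(c(0.2, 0.8), c(0)), "equal length")

  # constant event-rate predictor can never beat the true probabilities
  cohort <- generate_cohort(sim_config(n = 20000, seed = 77))
  y <- cohort$endpoint_drawn
  expect_gte(brier_score(rep(mean(y), length(y)), y),
             brier_score(cohort$true_risk, y))
})

test_that("AUROC equals exhaustive pair enumeration, with and without ties", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0))$auroc, 1.0)
  expect_equal(auroc(rep(0.4, 10), rbinom(10, 1, 0.5) * 0 + rep(c(0, 1), 5))$auroc, 0.5)

  # 8-point mixed set with a tie (worked example)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.5, 0.2)
  y <- c(0, 0, 1, 1, 0, 1, 0, 1)
  expect_equal(auroc(s, y)$auroc, auc_pairs(s, y))

  # property: random inputs with heavy ties, n up to 200
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(auroc(s, y)$auroc, auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(7)
  s <- runif(300)
  y <- rbinom(300, 1, s)
  a0 <- auroc(s, y)$auroc
  expect_equal(auroc(qlogis(s), y)$auroc, a0)
  expect_equal(auroc(s^3 + 2 * s, y)$auroc, a0)
  expect_equal(auroc(rank(s, ties.method = "average"), y)$auroc, a0)
})

test_that("DeLong interval matches the independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:5) {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    if (sum(y) < 2 || sum(y) > n - 2) next
    s <- runif(n) + 0.5 * y
    got <- auroc(s, y)
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                         method = "delong"))
    expect_equal(got$auroc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(got$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(got$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(3)
  s <- sample(seq(0, 1, 0.05), 100, replace = TRUE)
  y <- rbinom(100, 1, 0.5)
  pts <- auroc(s, y)$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))

  expect_error(auroc(s, rep(0, 100)), "positive")
})

test_that("calibration assessment recovers the generating calibration", {
  set.seed(500)
  n <- 50000
  s <- plogis(rnorm(n, -1.5, 1.2))
  y <- rbinom(n, 1, s)
  cal <- calibration_assessment(s, y)
  expect_lt(abs(cal$cal_slope - 1), 0.1)
  expect_lt(abs(cal$citl), 0.05)
  expect_lt(abs(cal$eo_ratio - 1), 0.05)

  # doubling in logit space roughly halves the fitted slope
  s2 <- plogis(2 * qlogis(s))
  cal2 <- calibration_assessment(s2, y)
  expect_lt(abs(cal2$cal_slope - 0.5), 0.05)

  # E:O is the ratio of means by definition
  cal3 <- suppressWarnings(calibration_assessment(c(0.2, 0.2), c(0, 1)))
  expect_equal(cal3$eo_ratio, 0.2 / 0.5)
  expect_true(is.na(cal3$cal_slope))

  expect_error(calibration_assessment(c(0.2, 0.3), c(0, 0)), "classes")
})

test_that("reliability-curve bins partition the sample", {
  set.seed(8)
  s <- runif(137)
  y <- rbinom(137, 1, s)
  cal <- calibration_assessment(s, y, n_bins = 10)
  expect_equal(sum(cal$curve$n), 137)
  expect_equal(nrow(cal$curve), 10)
  expect_true(all(diff(cal$curve$mean_predicted) > 0))
})

test_that("stratification tables conserve totals and reproduce counts", {
  fix <- counts_to_scores(neonatal_counts())
  tab <- stratification_table(fix$scores, fix$outcomes, fix$thresholds)
  expect_equal(tab$n_total, c(178L, 192L, 113L))
  expect_equal(tab$n_endpoint, c(12L, 43L, 77L))
  expect_equal(sum(tab$n_total), length(fix$scores))
  expect_equal(sum(tab$n_endpoint), sum(fix$outcomes))

  thr <- threshold_pair(0.5, 0.8)
  all_low <- stratification_table(runif(50, 0, 0.4), rbinom(50, 1, 0.2), thr)
  expect_equal(all_low$n_total, c(50L, 0L, 0L))
})

test_that("table metrics equal metrics recomputed from raw pairs", {
  set.seed(15)
  s <- runif(400)
  y <- rbinom(400, 1, s)
  thr <- threshold_pair(0.3, 0.7)
  m <- table_metrics(stratification_table(s, y, thr))

  pos_low <- s > thr$low
  expect_equal(m$sensitivity[m$boundary == "non_urgent"],
               sum(pos_low & y == 1) / sum(y == 1))
  expect_equal(m$specificity[m$boundary == "non_urgent"],
               sum(!pos_low & y == 0) / sum(y == 0))
  pos_high <- s > thr$high
  expect_equal(m$ppv[m$boundary == "emergency"],
               sum(pos_high & y == 1) / sum(pos_high))
  expect_equal(m$lr_pos[m$boundary == "emergency"],
               (sum(pos_high & y == 1) / sum(y == 1)) /
                 (sum(pos_high & y == 0) / sum(y == 0)))
})

test_that("Wilson intervals contain the estimate and shrink with n", {
  m <- table_metrics(stratification_table_from_counts(
    c(50, 30, 20), c(5, 10, 15), threshold_pair(0.1, 0.4)))
  for (met in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_true(all(m[[paste0(met, "_low")]] <= m[[met]] + 1e-12))
    expect_true(all(m[[paste0(met, "_high")]] >= m[[met]] - 1e-12))
  }
  # width decreases as counts scale up at fixed proportions
  m10 <- table_metrics(stratification_table_from_counts(
    10 * c(50, 30, 20), 10 * c(5, 10, 15), threshold_pair(0.1, 0.4)))
  expect_true(all(
    (m10$sensitivity_high - m10$sensitivity_low) <
      (m$sensitivity_high - m$sensitivity_low)
  ))

  # perfect sensitivity when there are no false negatives
  perfect <- table_metrics(stratification_table_from_counts(
    c(40, 30, 30), c(0, 25, 30), threshold_pair(0.1, 0.4)))
  expect_equal(perfect$sensitivity[perfect$boundary == "non_urgent"], 1.0)

  # zero denominator yields NA, not zero
  degen <- table_metrics(stratification_table_from_counts(
    c(50, 50, 0), c(10, 20, 0), threshold_pair(0.1, 0.4)))
  expect_true(is.na(degen$ppv[degen$boundary == "emergency"]))
})

test_that("threshold selection meets its own targets on the selection data", {
  set.seed(23)
  cohort <- generate_cohort(neonatal_sim_config(n = 3000, seed = 23))
  s <- cohort$true_risk
  y <- cohort$endpoint_drawn
  thr <- select_thresholds(s, y, 0.90, 0.90)
  expect_lt(thr$low, thr$high)
  pos <- s[y == 1]; neg <- s[y == 0]
  expect_gte(mean(pos > thr$low), 0.90)
  expect_gte(mean(neg <= thr$high), 0.90)

  # perfectly separated: low lands at the largest negative-class score
  s2 <- c(rep(0.1, 5), 0.15, rep(0.9, 5))
  y2 <- c(rep(0, 6), rep(1, 5))
  thr2 <- select_thresholds(s2, y2, sens_target = 1.0, spec_target = 1.0)
  expect_equal(thr2$low, 0.15)
  expect_gte(mean(s2[y2 == 1] > thr2$low), 1.0)

  # vacuous sensitivity target: low is the largest candidate below high
  thr3 <- select_thresholds(s2, y2, sens_target = 0, spec_target = 1.0)
  expect_equal(thr3$high, 0.15)
  expect_equal(thr3$low, 0.1)

  # a case scoring 0 can never be caught by "above threshold = positive"
  expect_error(select_thresholds(c(0, 0.5, 0.6), c(1, 0, 0), sens_target = 0.9),
               "unattainable")
})
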