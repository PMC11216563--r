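# Internal validation: stratified k-fold cross-validation with pooled
# out-of-fold metrics, and Harrell bootstrap optimism correction.

#' Stratified k-fold cross-validation of a revised model
#'
#' Assigns records to `k` folds stratified by outcome (so rare-event cohorts
#' do not produce single-class folds), refits the full model (revision) on
#' each training set, scores the held-out fold, and pools by concatenating
#' the out-of-fold predictions before computing metrics once. Pooled
#' sensitivity/specificity/NPV/PPV are evaluated at thresholds selected once
#' on the pooled out-of-fold predictions (set `per_fold_thresholds = TRUE` to
#' select within each fold instead).
#'
#' @param cohort Imputed cohort tibble with an `endpoint` column.
#' @param template [coefficient_set()] declaring predictors/transforms.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param sens_target,spec_target Threshold-selection targets.
#' @param per_fold_thresholds Select thresholds within each fold rather than
#'   once on the pooled predictions.
#' @return An object of class `cross_validation`: `pooled` (tibble of pooled
#'   AUROC and category metrics), `per_fold` (per-fold AUROC), `folds`
#'   (assignment), `predictions` (out-of-fold scores), `thresholds`.
#' @export
cross_validate <- function(cohort, template, k = 10L, seed = 1L,
                           sens_target = 0.90, spec_target = 0.90,
                           per_fold_thresholds = FALSE) {
  if (!"endpoint" %in% names(cohort)) {
    abort("Cohort has no `endpoint` column; run derive_composite_endpoint().")
  }
  y <- cohort$endpoint
  n <- length(y)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` cannot exceed the number of records.")
  set.seed(seed)
  # stratified by outcome: shuffle within each class, then deal folds
  # round-robin across the concatenated classes so every fold is non-empty
  # and events spread as evenly as possible
  idx_all <- c(sample(which(y == 1)), sample(which(y == 0)))
  fold <- integer(n)
  fold[idx_all] <- rep_len(seq_len(k), n)
  ev_per_fold <- tapply(y, fold, sum)
  # training sets (the fold's complement) must contain both classes
  if (any(sum(y) - ev_per_fold == 0) ||
      any(sum(1 - y) - tapply(1 - y, fold, sum) == 0)) {
    abort("A training fold contains a single outcome class; use a smaller k.")
  }
  if (any(ev_per_fold < 5)) {
    warn("Fewer than 5 events in at least one fold; estimates may be unstable.")
  }

  oof <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- revise_model(cohort[!test, , drop = FALSE], template,
                        outcomes = y[!test])
    p <- predict_risk(cohort[test, , drop = FALSE], fit)$probability
    oof[test] <- p
    per_fold[[f]] <- tibble::tibble(
      fold = f, n = sum(test), n_events = sum(y[test]),
      # per-fold AUROC is undefined when the held-out fold is single-class
      auroc = if (all(y[test] == 0) || all(y[test] == 1)) NA_real_
              else auc_rank(p, y[test])
    )
  }
  thr <- if (!per_fold_thresholds) {
    select_thresholds(oof, y, sens_target, spec_target)
  } else NULL

  pooled_disc <- auroc(oof, y)
  if (per_fold_thresholds) {
    # Per-fold selection: categorize each fold with its own thresholds.
    cats <- integer(n)
    for (f in seq_len(k)) {
      test <- fold == f
      thr_f <- select_thresholds(oof[test], y[test], sens_target, spec_target)
      cats[test] <- as.integer(categorize(oof[test], thr_f))
    }
    tab <- stratification_table_from_counts(
      tabulate(cats, 3),
      vapply(1:3, function(i) sum(y[cats == i]), numeric(1)),
      threshold_pair(0.5 - 1e-9, 0.5, provenance = "per-fold selection")
    )
  } else {
    tab <- stratification_table(oof, y, thr)
  }
  metrics <- table_metrics(tab)
  structure(
    list(
      k = k, seed = seed,
      pooled = tibble::tibble(
        auroc = pooled_disc$auroc,
        auroc_low = pooled_disc$ci_low, auroc_high = pooled_disc$ci_high
      ),
      category_metrics = metrics,
      per_fold = dplyr::bind_rows(per_fold),
      folds = fold,
      predictions = oof,
      thresholds = thr,
      table = tab
    ),
    class = "cross_validation"
  )
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf("<cross_validation: k=%d, pooled AUROC %.3f (%.3f-%.3f)>\n",
              x$k, x$pooled$auroc, x$pooled$auroc_low, x$pooled$auroc_high))
  invisible(x)
}

#' @exportS3Method
tidy.cross_validation <- function(x, ...) x$per_fold

#' @exportS3Method
glance.cross_validation <- function(x, ...) {
  dplyr::mutate(x$pooled, k = x$k, seed = x$seed)
}

#' Bootstrap optimism-corrected AUROC
#'
#' Harrell's optimism correction: the model is refitted on each bootstrap
#' resample; optimism is the mean difference between the resample-apparent
#' AUROC and the AUROC of the resample model evaluated on the original data;
#' the corrected estimate is the apparent AUROC minus the mean optimism.
#' Resamples with a single outcome class or failed fits are skipped and
#' counted.
#'
#' @param cohort Imputed cohort tibble with an `endpoint` column.
#' @param template [coefficient_set()] declaring predictors/transforms.
#' @param B Bootstrap replicates (at least 50).
#' @param seed Resampling seed.
#' @return A tibble: `apparent`, `optimism`, `corrected`, `B_used`,
#'   `B_skipped`.
#' @export
bootstrap_validate <- function(cohort, template, B = 200L, seed = 1L) {
  if (B < 50) abort("`B` must be at least 50.")
  if (!"endpoint" %in% names(cohort)) {
    abort("Cohort has no `endpoint` column; run derive_composite_endpoint().")
  }
  y <- cohort$endpoint
  n <- length(y)
  full <- revise_model(cohort, template)
  p_app <- predict_risk(cohort, full)$probability
  apparent <- auc_rank(p_app, y)

  set.seed(seed)
  opt <- numeric(0)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (all(yb == 0) || all(yb == 1)) {
      skipped <- skipped + 1L
      next
    }
    fit_b <- tryCatch(
      suppressWarnings(revise_model(cohort[idx, , drop = FALSE], template,
                                    outcomes = yb)),
      error = function(e) NULL
    )
    if (is.null(fit_b)) {
      skipped <- skipped + 1L
      next
    }
    auc_boot <- auc_rank(predict_risk(cohort[idx, , drop = FALSE], fit_b)$probability, yb)
    auc_orig <- auc_rank(predict_risk(cohort, fit_b)$probability, y)
    opt <- c(opt, auc_boot - auc_orig)
  }
  if (length(opt) == 0) abort("All bootstrap resamples were degenerate.")
  tibble::tibble(
    apparent = apparent,
    optimism = mean(opt),
    corrected = apparent - mean(opt),
    B_used = length(opt),
    B_skipped = skipped
  )
}
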