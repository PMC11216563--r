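# End-to-end pipeline: read -> endpoint -> subset -> impute -> score ->
# validate (-> optionally update / cross-validate), plus report rendering.

#' Run the full validation pipeline
#'
#' Composes the package's stages on a cohort CSV (or an in-memory cohort):
#' read, composite-endpoint derivation, age-group subsetting, median/mode
#' imputation, scoring with a coefficient set, validation metrics
#' (Brier, AUROC with CI, calibration, stratification table and category
#' metrics), and optionally the update cascade and cross-validation. Writes a
#' machine-readable JSON report plus rendered text tables and curve CSVs if
#' `out_dir` is given; every number in the rendered tables is recomputable
#' from the JSON twin. Outputs contain the seed and a config echo for
#' provenance, and no timestamps, so identical config + seed gives identical
#' output bytes.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `cohort` (CSV path) or `cohort_data` (data frame); optional `schema`,
#'   `age_unit`; `model` (coefficient-set JSON path, or `"neonatal"`);
#'   `age_group` and `age_mode`; either `thresholds = c(low, high)` or
#'   `select_thresholds = list(sens_target=, spec_target=)`;
#'   `n_bins`; `update = TRUE/FALSE`; `crossval = list(k=)` or `NULL`;
#'   `seed`; `out_dir` (optional).
#' @return A `validation_report` object (invisibly if written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)  # remove partial outputs
    abort(sprintf("Pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)))
  }

  cohort <- tryCatch({
    if (!is.null(config$cohort_data)) tibble::as_tibble(config$cohort_data)
    else read_cohort(config$cohort, schema = unlist(config$schema),
                     age_unit = config$age_unit %||% "months")
  }, error = function(e) on_fail("read", e))

  cohort <- tryCatch(derive_composite_endpoint(cohort),
                     error = function(e) on_fail("endpoint", e))
  counts <- list(read = nrow(cohort))

  if (!is.null(config$age_group)) {
    cohort <- tryCatch(
      subset_by_age(cohort, config$age_group,
                    mode = config$age_mode %||% "inclusive"),
      error = function(e) on_fail("subset", e))
  }
  counts$subset <- nrow(cohort)
  cohort <- tryCatch(impute_missing(cohort),
                     error = function(e) on_fail("impute", e))

  model <- tryCatch({
    m <- config$model %||% "neonatal"
    if (inherits(m, "coefficient_set")) m
    else if (identical(m, "neonatal")) neonatal_model()
    else read_coefficient_set(m)
  }, error = function(e) on_fail("model", e))

  scored <- tryCatch(predict_risk(cohort, model),
                     error = function(e) on_fail("score", e))
  y <- scored$endpoint
  p <- scored$probability

  report <- tryCatch({
    thr <- if (!is.null(config$thresholds)) {
      threshold_pair(config$thresholds[[1]], config$thresholds[[2]],
                     provenance = "config")
    } else {
      st <- config$select_thresholds %||% list()
      select_thresholds(p, y, st$sens_target %||% 0.90,
                        st$spec_target %||% 0.90)
    }
    n_bins <- config$n_bins %||% 10L
    disc <- auroc(p, y, seed = seed)
    cal <- calibration_assessment(p, y, n_bins = n_bins)
    tab <- stratification_table(p, y, thr)
    summary_tbl <- cohort_summary(scored)
    cascade <- if (isTRUE(config$update)) {
      run_update_cascade(cohort, model, n_bins = n_bins)
    } else NULL
    cv <- if (!is.null(config$crossval)) {
      cross_validate(cohort, model, k = config$crossval$k %||% 10L,
                     seed = seed)
    } else NULL
    structure(
      list(
        cohort_summary = summary_tbl,
        record_counts = counts,
        brier = brier_score(p, y),
        discrimination = tidy(disc),
        calibration = tidy(cal),
        calibration_curve = cal$curve,
        thresholds = thr,
        stratification = tibble::as_tibble(tab),
        category_metrics = table_metrics(tab),
        cascade = if (!is.null(cascade)) cascade$stages else NULL,
        cascade_curves = if (!is.null(cascade)) cascade$curves else NULL,
        crossval = if (!is.null(cv)) glance(cv) else NULL,
        provenance = list(
          seed = seed,
          model = model$label,
          muac_unit = model$muac_unit,
          package_version = as.character(utils::packageVersion("pedtriage")),
          config = config[setdiff(names(config), "cohort_data")]
        )
      ),
      class = "validation_report"
    )
  }, error = function(e) on_fail("validate", e))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- write_report(report, out_dir)
  }
  invisible(report)
}

# Per-age-group counts and endpoint proportions (the cohort-summary block).
cohort_summary <- function(cohort) {
  groups <- c("<1m", "<=2m", "<=6m", "<5y")
  purrr::map_dfr(groups, function(g) {
    sub <- subset_by_age(cohort, g, mode = "inclusive")
    tibble::tibble(
      age_group = g,
      n = nrow(sub),
      n_endpoint = sum(sub$endpoint),
      prevalence = if (nrow(sub)) mean(sub$endpoint) else NA_real_
    )
  })
}

#' Write a validation report to disk
#'
#' Writes `report.json` (full precision), `report.txt` (rendered tables),
#' `calibration_curve.csv` and `category_metrics.csv` into `out_dir`.
#'
#' @param report A `validation_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  json_path <- file.path(out_dir, "report.json")
  txt_path <- file.path(out_dir, "report.txt")
  curve_path <- file.path(out_dir, "calibration_curve.csv")
  metrics_path <- file.path(out_dir, "category_metrics.csv")
  serializable <- list(
    cohort_summary = report$cohort_summary,
    record_counts = report$record_counts,
    brier = report$brier,
    discrimination = report$discrimination,
    calibration = report$calibration,
    calibration_curve = report$calibration_curve,
    thresholds = unclass(report$thresholds),
    stratification = report$stratification,
    category_metrics = report$category_metrics,
    cascade = report$cascade,
    crossval = report$crossval,
    provenance = report$provenance
  )
  jsonlite::write_json(serializable, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(c(
    render_table(report, style = "table1"), "",
    render_table(report, style = "table2")
  ), txt_path)
  readr::write_csv(report$calibration_curve, curve_path, progress = FALSE)
  readr::write_csv(report$category_metrics, metrics_path, progress = FALSE)
  invisible(c(json_path, txt_path, curve_path, metrics_path))
}

#' Render report blocks as publication-style text tables
#'
#' `"table1"` renders the per-age-group cohort summary; `"table2"` and
#' `"table3"` render the risk-stratification block (category counts and
#' classification metrics; the `table3` style adds likelihood-ratio rows).
#' Rounding happens only here (round-half-even; 2 decimals for metrics, 1 for
#' percentages) — computed values are never rounded upstream.
#'
#' @param report A `validation_report`.
#' @param style `"table1"`, `"table2"` or `"table3"`.
#' @return Character vector of table lines.
#' @export
render_table <- function(report, style = c("table2", "table1", "table3")) {
  style <- match.arg(style)
  fmt2 <- function(x) ifelse(is.na(x), "—", sprintf("%.2f", round(x, 2)))
  pct1 <- function(x) ifelse(is.na(x), "—", sprintf("%.1f", round(100 * x, 1)))
  ci2 <- function(est, lo, hi) {
    ifelse(is.na(est), "—",
           sprintf("%s (%s–%s)", fmt2(est), fmt2(lo), fmt2(hi)))
  }
  if (style == "table1") {
    cs <- report$cohort_summary
    return(c(
      "Cohort summary (inclusive age groups)",
      sprintf("%-10s %8s %10s %12s", "group", "n", "endpoint", "endpoint %"),
      sprintf("%-10s %8d %10d %12s", cs$age_group, cs$n, cs$n_endpoint,
              pct1(cs$prevalence))
    ))
  }
  tab <- report$stratification
  m <- report$category_metrics
  thr <- report$thresholds
  n_all <- sum(tab$n_total)
  header <- sprintf("%-28s %18s %18s %18s", "",
                    "Non-urgent", "Priority", "Emergency")
  thr_row <- sprintf("%-28s %18s %18s %18s", "Risk threshold",
                     sprintf("<= %.2f", thr$low),
                     sprintf(">%.2f <= %.2f", thr$low, thr$high),
                     sprintf("> %.2f", thr$high))
  n_row <- sprintf("%-28s %18s %18s %18s", "Participant, n (%)",
                   sprintf("%d (%s)", tab$n_total[1], pct1(tab$n_total[1] / n_all)),
                   sprintf("%d (%s)", tab$n_total[2], pct1(tab$n_total[2] / n_all)),
                   sprintf("%d (%s)", tab$n_total[3], pct1(tab$n_total[3] / n_all)))
  ep_pct <- ifelse(tab$n_total > 0, tab$n_endpoint / tab$n_total, NA_real_)
  e_row <- sprintf("%-28s %18s %18s %18s", "With endpoint, n (%)",
                   sprintf("%d (%s)", tab$n_endpoint[1], pct1(ep_pct[1])),
                   sprintf("%d (%s)", tab$n_endpoint[2], pct1(ep_pct[2])),
                   sprintf("%d (%s)", tab$n_endpoint[3], pct1(ep_pct[3])))
  metric_row <- function(label, est, lo, hi) {
    sprintf("%-28s %18s %18s %18s", label,
            ci2(est[1], lo[1], hi[1]), ci2(est[2], lo[2], hi[2]),
            ci2(est[3], lo[3], hi[3]))
  }
  lines <- c(
    "Risk stratification into triage categories",
    header, thr_row, n_row, e_row,
    metric_row("Sensitivity (95% CI)", m$sensitivity, m$sensitivity_low, m$sensitivity_high),
    metric_row("Specificity (95% CI)", m$specificity, m$specificity_low, m$specificity_high),
    metric_row("NPV (95% CI)", m$npv, m$npv_low, m$npv_high),
    metric_row("PPV (95% CI)", m$ppv, m$ppv_low, m$ppv_high)
  )
  if (style == "table3") {
    lines <- c(
      lines,
      metric_row("Negative LR (95% CI)", m$lr_neg, m$lr_neg_low, m$lr_neg_high),
      metric_row("Positive LR (95% CI)", m$lr_pos, m$lr_pos_low, m$lr_pos_high)
    )
  }
  lines
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_table(x, "table1"), sep = "\n")
  cat("\n")
  cat(render_table(x, "table3"), sep = "\n")
  cat(sprintf("\nBrier %.4f | AUROC %.3f (%.3f-%.3f) | slope %.3f | E:O %.3f\n",
              x$brier, x$discrimination$auroc, x$discrimination$ci_low,
              x$discrimination$ci_high, x$calibration$cal_slope,
              x$calibration$eo_ratio))
  invisible(x)
}
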