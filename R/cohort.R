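#' Read a pediatric cohort from CSV
#'
#' Reads a delimited cohort (one row per child) into a typed tibble using the
#' canonical column names
#' `id, age_months, heart_rate, temperature_c, muac_mm, spo2, parent_concern,
#' difficulty_breathing, oedema, pallor, sex, site, admitted, los_hours,
#' readmit_48h, readmit_late, died`. Non-canonical files are mapped with
#' `schema`. Unparseable or out-of-range cells become missing; a per-column
#' parse report is attached as the `"parse_report"` attribute (see
#' [parse_report()]).
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical names to
#'   the column names used in the file, e.g. `c(age_months = "age_mo")`.
#' @param age_unit Unit of the age column in the file: `"months"` (default),
#'   `"days"` or `"years"`; converted to months internally (days / 30.4375,
#'   years * 12).
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, schema = NULL,
                        age_unit = c("months", "days", "years")) {
  age_unit <- match.arg(age_unit)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (nrow(raw) == 0L) abort(sprintf("Empty cohort file: %s", path))

  canonical <- c("id", "age_months", predictor_columns()[-1], "sex", "site",
                 outcome_columns())
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        abort(sprintf("Schema maps `%s` to `%s`, which is not in the file.",
                      canon, schema[[canon]]))
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- c("id", "age_months", predictor_columns()[-1],
                "admitted", "readmit_48h", "died")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (opt in setdiff(canonical, names(raw))) raw[[opt]] <- NA_character_

  num <- function(x) suppressWarnings(as.numeric(x))
  bin <- function(x) {
    v <- num(x)
    v[!v %in% c(0, 1)] <- NA_real_
    v
  }
  age <- num(raw$age_months)
  age <- switch(age_unit, months = age, days = age / 30.4375, years = age * 12)
  age[age < 0] <- NA_real_
  spo2 <- num(raw$spo2)
  spo2[spo2 <= 0 | spo2 > 100] <- NA_real_
  los <- num(raw$los_hours)
  los[los < 0] <- NA_real_

  cohort <- tibble::tibble(
    id = as.character(raw$id),
    age_months = age,
    heart_rate = num(raw$heart_rate),
    temperature_c = num(raw$temperature_c),
    muac_mm = num(raw$muac_mm),
    spo2 = spo2,
    parent_concern = bin(raw$parent_concern),
    difficulty_breathing = bin(raw$difficulty_breathing),
    oedema = bin(raw$oedema),
    pallor = bin(raw$pallor),
    sex = ifelse(raw$sex %in% c("male", "female"), raw$sex, "unknown"),
    site = as.character(raw$site),
    admitted = bin(raw$admitted),
    los_hours = los,
    readmit_48h = bin(raw$readmit_48h),
    readmit_late = bin(raw$readmit_late),
    died = bin(raw$died)
  )
  if (anyDuplicated(stats::na.omit(cohort$id)) > 0) {
    warn("Duplicate record ids in cohort.")
  }
  report <- tibble::tibble(
    column = names(cohort),
    n_missing = vapply(cohort, function(x) sum(is.na(x)), integer(1))
  )
  attr(cohort, "parse_report") <- report
  attr(cohort, "provenance") <- path
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the canonical columns with full
#' precision so a write-read round trip preserves every finite value.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' Per-column parse report of a cohort read
#'
#' @param cohort A cohort returned by [read_cohort()].
#' @return A tibble with `column` and `n_missing`.
#' @export
parse_report <- function(cohort) {
  attr(cohort, "parse_report") %||%
    tibble::tibble(
      column = names(cohort),
      n_missing = vapply(cohort, function(x) sum(is.na(x)), integer(1))
    )
}

#' Derive the composite endpoint
#'
#' The primary outcome is a composite: hospital admission lasting 24 hours or
#' more, readmission within 48 hours of enrollment, or death (in-hospital or
#' post-discharge). Adds an `endpoint` column (0/1). Records whose endpoint
#' cannot be determined (missing admission/readmission/death status, or
#' admitted with unknown length of stay) are dropped with a warning; the
#' endpoint prevalence of the returned cohort is attached as the
#' `"prevalence"` attribute.
#'
#' @param cohort A cohort tibble with outcome columns.
#' @return The cohort with an `endpoint` column added.
#' @export
derive_composite_endpoint <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c("admitted", "los_hours", "readmit_48h", "died")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing outcome column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  undeterminable <- is.na(cohort$admitted) | is.na(cohort$readmit_48h) |
    is.na(cohort$died) |
    (cohort$admitted == 1 & is.na(cohort$los_hours) &
       !(cohort$readmit_48h %in% 1) & !(cohort$died %in% 1))
  if (all(undeterminable)) {
    abort("Endpoint cannot be determined for any record (outcome fields missing).")
  }
  if (any(undeterminable)) {
    warn(sprintf("Excluding %d record(s) with undeterminable endpoint.",
                 sum(undeterminable)))
    cohort <- cohort[!undeterminable, , drop = FALSE]
  }
  los <- ifelse(is.na(cohort$los_hours), 0, cohort$los_hours)
  cohort$endpoint <- as.numeric(
    (cohort$admitted == 1 & los >= 24) | cohort$readmit_48h == 1 | cohort$died == 1
  )
  attr(cohort, "prevalence") <- mean(cohort$endpoint)
  cohort
}

#' Age-group subsetting
#'
#' Inclusive groups nest (`"<1m"` within `"<=2m"` within `"<=6m"` within
#' `"<5y"`); exclusive bands (`"<1m"`, `"1-2m"`, `">2-6m"`, `">6m-<5y"`)
#' partition the under-5 cohort. Boundary convention: `"<1m"` is age < 1.0
#' month, `"<=2m"` is age <= 2.0, `"<=6m"` is age <= 6.0, `"<5y"` is
#' age < 60.0; the exclusive bands are \[0,1), \[1,2\], (2,6\], (6,60).
#'
#' @param cohort A cohort tibble with non-missing `age_months`.
#' @param group Group label (see above).
#' @param mode `"inclusive"` or `"exclusive"`.
#' @return The subset cohort tibble.
#' @export
subset_by_age <- function(cohort, group, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  cohort <- tibble::as_tibble(cohort)
  if (anyNA(cohort$age_months)) {
    abort("`age_months` must be non-missing for age subsetting.")
  }
  a <- cohort$age_months
  keep <- if (mode == "inclusive") {
    switch(group,
      "<1m" = a < 1,
      "<=2m" = a <= 2,
      "<=6m" = a <= 6,
      "<5y" = a < 60,
      abort(sprintf("Unknown inclusive age group: %s", group))
    )
  } else {
    switch(group,
      "<1m" = a < 1,
      "1-2m" = a >= 1 & a <= 2,
      ">2-6m" = a > 2 & a <= 6,
      ">6m-<5y" = a > 6 & a < 60,
      abort(sprintf("Unknown exclusive age band: %s", group))
    )
  }
  cohort[keep, , drop = FALSE]
}

#' Exclusive age band of each record
#'
#' @param cohort A cohort tibble.
#' @return Factor with levels `"<1m"`, `"1-2m"`, `">2-6m"`, `">6m-<5y"`
#'   (records at or above 60 months are `NA`).
#' @export
age_bands <- function(cohort) {
  a <- cohort$age_months
  out <- dplyr::case_when(
    a < 1 ~ "<1m",
    a <= 2 ~ "1-2m",
    a <= 6 ~ ">2-6m",
    a < 60 ~ ">6m-<5y",
    TRUE ~ NA_character_
  )
  factor(out, levels = c("<1m", "1-2m", ">2-6m", ">6m-<5y"))
}

#' Median/mode imputation of predictors
#'
#' Fills missing continuous predictors with the column median and missing
#' binary predictors with the column mode (ties broken toward 0). Outcome
#' fields are never imputed. Intended to run on the analysis cohort after age
#' subsetting (impute whole datasets before subsetting if preferred).
#'
#' @param cohort A cohort tibble.
#' @return The imputed cohort, with an `"imputation_report"` attribute: a
#'   tibble of `column`, `fill_value`, `n_filled` for each imputed column.
#' @export
impute_missing <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  report <- list()
  for (col in intersect(continuous_predictors(), names(cohort))) {
    nmiss <- sum(is.na(cohort[[col]]))
    if (nmiss == 0) next
    if (nmiss == nrow(cohort)) abort(sprintf("Column `%s` is fully missing; cannot impute.", col))
    fill <- median(cohort[[col]], na.rm = TRUE)
    cohort[[col]][is.na(cohort[[col]])] <- fill
    report[[col]] <- tibble::tibble(column = col, fill_value = fill, n_filled = nmiss)
  }
  for (col in intersect(binary_predictors(), names(cohort))) {
    nmiss <- sum(is.na(cohort[[col]]))
    if (nmiss == 0) next
    if (nmiss == nrow(cohort)) abort(sprintf("Column `%s` is fully missing; cannot impute.", col))
    x <- cohort[[col]][!is.na(cohort[[col]])]
    fill <- if (mean(x) > 0.5) 1 else 0  # mode; tie -> 0
    cohort[[col]][is.na(cohort[[col]])] <- fill
    report[[col]] <- tibble::tibble(column = col, fill_value = fill, n_filled = nmiss)
  }
  attr(cohort, "imputation_report") <-
    if (length(report)) dplyr::bind_rows(report) else
      tibble::tibble(column = character(), fill_value = numeric(), n_filled = integer())
  cohort
}

#' Compare endpoint proportions across an age split
#'
#' Two-sided Fisher's exact test of the composite-endpoint proportion between
#' children above the age split and those at or below it (default split: six
#' months). Two-sided p-value is the sum of hypergeometric probabilities of
#' tables at most as probable as the observed one.
#'
#' @param cohort A cohort tibble with `age_months` and an `endpoint` column
#'   (derived with [derive_composite_endpoint()] if absent).
#' @param split_age_months Age split in months (default 6).
#' @return A one-row tibble: stratum counts and proportions, the odds-ratio
#'   estimate and the two-sided exact p-value. The underlying 2x2 table is
#'   attached as attribute `"table"`.
#' @export
compare_endpoint_proportions <- function(cohort, split_age_months = 6) {
  if (!"endpoint" %in% names(cohort)) cohort <- derive_composite_endpoint(cohort)
  older <- cohort$age_months > split_age_months
  if (!any(older) || all(older)) {
    abort("Both age strata must be non-empty for the comparison.")
  }
  tab <- matrix(
    c(sum(cohort$endpoint[older] == 1), sum(cohort$endpoint[older] == 0),
      sum(cohort$endpoint[!older] == 1), sum(cohort$endpoint[!older] == 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(stratum = c("older", "younger"), endpoint = c("yes", "no"))
  )
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  out <- tibble::tibble(
    n_older = sum(older),
    n_younger = sum(!older),
    prop_older = mean(cohort$endpoint[older]),
    prop_younger = mean(cohort$endpoint[!older]),
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    method = "Fisher exact (two-sided)"
  )
  attr(out, "table") <- tab
  out
}
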