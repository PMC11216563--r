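test_that("CSV round trip preserves every field and reports missing cells", {
  cohort <- make_tiny_cohort(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), ignore_attr = TRUE)

  # blank a cell and re-read: field missing, parse report counts it
  raw <- readLines(path)
  raw[2] <- sub(",98,", ",,", raw[2], fixed = TRUE)
  writeLines(raw, path)
  back2 <- read_cohort(path)
  expect_true(is.na(back2$spo2[1]))
  rep <- parse_report(back2)
  expect_equal(unname(rep$n_missing[rep$column == "spo2"]), 1L)

  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv")), "not found")
})

test_that("schema mapping and age-unit conversion work", {
  cohort <- make_tiny_cohort(3)
  names(cohort)[names(cohort) == "age_months"] <- "age_days"
  cohort$age_days <- c(15, 45, 370)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path)
  back <- read_cohort(path, schema = c(age_months = "age_days"), age_unit = "days")
  expect_equal(back$age_months, c(15, 45, 370) / 30.4375)
  # 30 days is a neonate under the documented convention
  expect_lt(30 / 30.4375, 1)
  expect_error(read_cohort(path, schema = c(age_months = "nope")), "not in the file")
})

test_that("missing required columns are named in the error", {
  cohort <- make_tiny_cohort(3)
  cohort$heart_rate <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path)
  expect_error(read_cohort(path), "heart_rate")
})

test_that("composite endpoint follows the admission/readmission/death rule", {
  base <- make_tiny_cohort(1)
  case <- function(admitted, los, readmit, died) {
    out <- base
    out$admitted <- admitted; out$los_hours <- los
    out$readmit_48h <- readmit; out$died <- died
    derive_composite_endpoint(out)$endpoint
  }
  expect_equal(case(1, 36, 0, 0), 1)  # long admission
  expect_equal(case(1, 10, 0, 0), 0)  # short admission does not qualify
  expect_equal(case(0, NA, 0, 0), 0)  # no qualifying event
  expect_equal(case(1, 10, 0, 1), 1)  # death qualifies regardless of stay
  expect_equal(case(0, NA, 1, 0), 1)  # early readmission qualifies

  # endpoint derivation is idempotent
  cohort <- derive_composite_endpoint(make_tiny_cohort(5))
  expect_equal(derive_composite_endpoint(cohort)$endpoint, cohort$endpoint)

  # undeterminable records are dropped with a warning; all-missing errors
  broken <- make_tiny_cohort(3)
  broken$admitted[1] <- NA
  expect_warning(out <- derive_composite_endpoint(broken), "Excluding 1")
  expect_equal(nrow(out), 2)
  broken$admitted <- NA_real_
  broken$readmit_48h <- NA_real_
  broken$died <- NA_real_
  expect_error(suppressWarnings(derive_composite_endpoint(broken)), "any record")
})

test_that("inclusive age groups nest and exclusive bands partition", {
  cohort <- make_tiny_cohort(8)
  cohort$age_months <- c(0.5, 0.9, 1.5, 2.0, 4, 6, 30, 59.9)
  ns <- vapply(c("<1m", "<=2m", "<=6m", "<5y"),
               function(g) nrow(subset_by_age(cohort, g)), numeric(1))
  expect_true(all(diff(ns) >= 0))
  expect_equal(unname(ns), c(2, 4, 6, 8))

  bands <- c("<1m", "1-2m", ">2-6m", ">6m-<5y")
  sizes <- vapply(bands, function(g)
    nrow(subset_by_age(cohort, g, mode = "exclusive")), numeric(1))
  expect_equal(sum(sizes), nrow(subset_by_age(cohort, "<5y")))
  expect_equal(sum(table(age_bands(cohort))), nrow(cohort))

  expect_equal(nrow(subset_by_age(
    dplyr::mutate(cohort, age_months = c(0.5, 1.5, 4, 48, 50, 51, 52, 53)), "<1m")), 1)
  expect_error(subset_by_age(cohort, "toddlers"), "Unknown")
})

test_that("median/mode imputation fills predictors and reports fills", {
  cohort <- make_tiny_cohort(5)
  cohort$heart_rate <- c(100, 110, 120, 130, NA)
  cohort$pallor <- c(0, 0, 1, NA, 0)
  out <- impute_missing(cohort)
  expect_equal(out$heart_rate[5], 115)
  expect_equal(out$pallor[4], 0)
  rep <- attr(out, "imputation_report")
  expect_setequal(rep$column, c("heart_rate", "pallor"))
  expect_equal(rep$n_filled, c(1L, 1L))

  # outcomes are never touched
  cohort$los_hours[2] <- NA
  expect_true(is.na(impute_missing(cohort)$los_hours[2]))

  # identity on complete data
  clean <- make_tiny_cohort(4)
  out2 <- impute_missing(clean)
  expect_equal(as.data.frame(out2), as.data.frame(clean), ignore_attr = TRUE)
  expect_equal(nrow(attr(out2, "imputation_report")), 0)

  broken <- make_tiny_cohort(3)
  broken$muac_mm <- NA_real_
  expect_error(impute_missing(broken), "muac_mm")
})

test_that("Fisher comparison matches hypergeometric enumeration", {
  # diagonal 2x2 tables with known enumeration
  for (fixture in list(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                       matrix(c(10, 0, 0, 10), 2, byrow = TRUE),
                       matrix(c(7, 3, 2, 8), 2, byrow = TRUE))) {
    p_enum <- fisher_enum(fixture)
    p_pkg <- stats::fisher.test(fixture)$p.value
    expect_equal(p_pkg, p_enum, tolerance = 1e-8)
  }

  # end-to-end on a cohort: older stratum all events, younger none
  cohort <- make_tiny_cohort(4)
  cohort$age_months <- c(2, 2, 12, 12)
  cohort$admitted <- c(0, 0, 1, 1)
  cohort$los_hours <- c(NA, NA, 48, 48)
  res <- compare_endpoint_proportions(cohort)
  expect_equal(res$p_value, fisher_enum(attr(res, "table")), tolerance = 1e-8)
  expect_equal(res$prop_older, 1)
  expect_equal(res$prop_younger, 0)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)

  # null case: identical proportions at large n
  big <- make_tiny_cohort(400)
  big$age_months <- rep(c(2, 12), each = 200)
  big$admitted <- rep(c(1, 0, 1, 0), 100)
  big$los_hours <- ifelse(big$admitted == 1, 48, NA)
  big$readmit_48h <- 0; big$died <- 0
  expect_gt(compare_endpoint_proportions(big)$p_value, 0.9)

  solo <- make_tiny_cohort(3)
  solo$age_months <- c(1, 2, 3)
  expect_error(compare_endpoint_proportions(solo), "non-empty")
})
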