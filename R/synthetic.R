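#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic outpatient cohort: the exclusive age-band mixture,
#' per-predictor distributions (optionally age-dependent), the true
#' coefficient set generating the outcome, site-level baseline-risk shifts on
#' the logit (emulating the miscalibration seen when a model meets a new
#' population with a different event rate), optional per-site coefficient
#' perturbations (emulating predictor-outcome associations that differ in the
#' new population), and a per-predictor missingness rate.
#'
#' Default age-band weights follow the structure of a multi-site under-5
#' outpatient cohort (about 3.5% neonates, 4% 1-2 months, 13% 2-6 months,
#' rest 6-59 months). Default vital-sign distributions are loosely matched to
#' plausible pediatric values (heart rate declining with age, MUAC growing
#' with age); they are configuration, not a claim of clinical realism.
#'
#' @param n Number of records.
#' @param seed Master seed; per-record streams are derived from it, so
#'   increasing `n` never reshuffles earlier records.
#' @param true_coefficients The data-generating [coefficient_set()].
#' @param age_weights Mixture weights over the exclusive bands
#'   `c("<1m", "1-2m", ">2-6m", ">6m-<5y")`; must sum to 1.
#' @param site_effects Named numeric vector of additive logit shifts per site;
#'   records are assigned sites with equal probability.
#' @param effect_perturbations Optional named list `site -> named multiplier
#'   vector` applied to the true coefficients for records at that site.
#' @param missingness_rate Per-predictor-cell missingness probability in
#'   \[0, 1).
#' @param endpoint_mix Proportions of endpoint-positive records realised as a
#'   long admission, a death, or an early readmission; must sum to 1. Outcome
#'   fields are back-filled through these mechanisms so that
#'   [derive_composite_endpoint()] recovers the drawn endpoint.
#' @param predictor_means Named list overriding the default continuous
#'   predictor location functions; each element is `function(age_months)`.
#' @param binary_prevalence Named numeric vector of prevalences for the four
#'   binary signs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n,
                       seed = 1L,
                       true_coefficients = synthetic_under5_model(),
                       age_weights = c("<1m" = 0.035, "1-2m" = 0.042,
                                       ">2-6m" = 0.132, ">6m-<5y" = 0.791),
                       site_effects = c(siteA = 0),
                       effect_perturbations = NULL,
                       missingness_rate = 0,
                       endpoint_mix = c(admission = 0.90, death = 0.05,
                                        readmission = 0.05),
                       predictor_means = NULL,
                       binary_prevalence = c(parent_concern = 0.25,
                                             difficulty_breathing = 0.20,
                                             oedema = 0.01,
                                             pallor = 0.10)) {
  if (n < 1) abort("`n` must be at least 1.")
  if (abs(sum(age_weights) - 1) > 1e-8 || any(age_weights < 0)) {
    abort("`age_weights` must be non-negative and sum to 1.")
  }
  if (missingness_rate < 0 || missingness_rate >= 1) {
    abort("`missingness_rate` must be in [0, 1).")
  }
  if (abs(sum(endpoint_mix) - 1) > 1e-8) abort("`endpoint_mix` must sum to 1.")
  stopifnot(inherits(true_coefficients, "coefficient_set"))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         true_coefficients = true_coefficients,
         age_weights = age_weights, site_effects = site_effects,
         effect_perturbations = effect_perturbations,
         missingness_rate = missingness_rate, endpoint_mix = endpoint_mix,
         predictor_means = predictor_means,
         binary_prevalence = binary_prevalence),
    class = "sim_config"
  )
}

# Default location functions for the continuous predictors (age in months).
default_predictor_means <- function() {
  list(
    heart_rate = function(age) 150 - 0.6 * age,
    temperature_c = function(age) rep(37.2, length(age)),
    muac_mm = function(age) 105 + 8 * sqrt(age),
    spo2_deficit_scale = function(age) rep(1.25, length(age))
  )
}

# Band boundaries (months) for the exclusive age bands.
band_ranges <- function() {
  list("<1m" = c(0, 1), "1-2m" = c(1, 2), ">2-6m" = c(2, 6),
       ">6m-<5y" = c(6, 60))
}

#' Generate a synthetic cohort with known true risks
#'
#' Draws age from the configured band mixture, predictors from their
#' (age-dependent) distributions, assigns a site, computes the true risk
#' `p = plogis(linear predictor + site shift)` under the configured true
#' coefficient set, draws the endpoint as Bernoulli(p), and back-fills the
#' outcome fields (admission + length of stay, death, or early readmission)
#' so that the endpoint pipeline — not a shortcut flag — recovers the drawn
#' endpoint. The true risk and linear predictor are kept in `true_risk` /
#' `true_lp` columns for oracle use.
#'
#' Reproducible: each record's values are drawn from a stream derived from
#' the master seed and the record index.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble with `true_risk`, `true_lp` and `endpoint_drawn`
#'   columns alongside the canonical cohort columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  means <- utils::modifyList(default_predictor_means(),
                             config$predictor_means %||% list())
  prev <- config$binary_prevalence
  seeds <- record_seeds(config$seed, n)

  # 14 uniforms per record: band, age-within-band, hr, temp, muac, spo2,
  # 4 binary signs, site, endpoint, mechanism, spare.
  U <- matrix(NA_real_, nrow = n, ncol = 14)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    U[i, ] <- runif(14)
  }

  bands <- names(config$age_weights)
  band_idx <- findInterval(U[, 1], cumsum(config$age_weights), left.open = TRUE) + 1L
  band_idx <- pmin(band_idx, length(bands))
  rng <- band_ranges()[bands]
  lo <- vapply(rng, `[`, numeric(1), 1)[band_idx]
  hi <- vapply(rng, `[`, numeric(1), 2)[band_idx]
  age <- lo + U[, 2] * (hi - lo)

  hr <- means$heart_rate(age) + qnorm(U[, 3]) * 18
  temp <- means$temperature_c(age) + qnorm(U[, 4]) * 0.9
  muac <- means$muac_mm(age) + qnorm(U[, 5]) * 12
  # SpO2: 100 minus a gamma-shaped deficit, clamped into (50, 100].
  deficit <- stats::qgamma(U[, 6], shape = 2, scale = means$spo2_deficit_scale(age))
  spo2 <- pmax(pmin(100 - deficit, 100), 50.5)

  cohort <- tibble::tibble(
    id = sprintf("sim%06d", seq_len(n)),
    age_months = age,
    heart_rate = pmax(hr, 40),
    temperature_c = pmin(pmax(temp, 33), 42),
    muac_mm = pmax(muac, 60),
    spo2 = spo2,
    parent_concern = as.numeric(U[, 7] < prev[["parent_concern"]]),
    difficulty_breathing = as.numeric(U[, 8] < prev[["difficulty_breathing"]]),
    oedema = as.numeric(U[, 9] < prev[["oedema"]]),
    pallor = as.numeric(U[, 10] < prev[["pallor"]]),
    sex = ifelse(U[, 14] < 0.53, "male", "female"),
    site = names(config$site_effects)[
      pmin(floor(U[, 11] * length(config$site_effects)) + 1L,
           length(config$site_effects))]
  )

  # True linear predictor, optionally with per-site coefficient perturbations.
  lp <- numeric(n)
  for (s in unique(cohort$site)) {
    rows <- cohort$site == s
    cs <- config$true_coefficients
    pert <- config$effect_perturbations[[s]]
    if (!is.null(pert)) {
      cs$coefficients[names(pert)] <- cs$coefficients[names(pert)] * pert
    }
    X <- build_design(cohort[rows, , drop = FALSE], cs)
    lp[rows] <- cs$intercept + drop(X %*% cs$coefficients) +
      config$site_effects[[s]]
  }
  p <- inv_logit(lp)
  event <- as.numeric(U[, 12] < p)

  # Back-fill outcome fields so derive_composite_endpoint() recovers `event`.
  mech_cut <- cumsum(config$endpoint_mix)
  mech <- findInterval(U[, 13], mech_cut, left.open = TRUE) + 1L
  mech <- pmin(mech, 3L)
  admitted <- numeric(n); los <- rep(NA_real_, n)
  readmit48 <- numeric(n); readmit_late <- numeric(n); died <- numeric(n)
  is_adm <- event == 1 & mech == 1L
  is_die <- event == 1 & mech == 2L
  is_rea <- event == 1 & mech == 3L
  admitted[is_adm] <- 1; los[is_adm] <- 48
  died[is_die] <- 1
  readmit48[is_rea] <- 1
  # A few non-endpoint short admissions keep the LOS >= 24h rule exercised.
  short <- event == 0 & U[, 13] < 0.05
  admitted[short] <- 1; los[short] <- 10

  cohort$admitted <- admitted
  cohort$los_hours <- los
  cohort$readmit_48h <- readmit48
  cohort$readmit_late <- readmit_late
  cohort$died <- died
  cohort$true_lp <- lp
  cohort$true_risk <- p
  cohort$endpoint_drawn <- event
  if (config$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, config$missingness_rate,
                                 seed = (config$seed + 7919) %% 2147483647)
  }
  attr(cohort, "sim_config") <- config
  cohort
}

#' Blank predictor cells at random
#'
#' Each of the nine predictor cells is independently set to missing with
#' probability `rate`; outcome fields are untouched. Reproducible from
#' `seed`.
#'
#' @param cohort A cohort tibble.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return The cohort with missing cells injected.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1).")
  if (rate == 0) return(cohort)
  cohort <- tibble::as_tibble(cohort)
  cols <- intersect(predictor_columns(), names(cohort))
  set.seed(seed)
  for (col in cols) {
    blank <- runif(nrow(cohort)) < rate
    cohort[[col]][blank] <- NA
  }
  cohort
}
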