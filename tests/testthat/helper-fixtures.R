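# Fixtures built in code: tiny cohorts, printed-table counts, oracles.

# A small fully-observed cohort with deterministic values.
make_tiny_cohort <- function(n = 5) {
  tibble::tibble(
    id = paste0("p", seq_len(n)),
    age_months = seq(0.5, by = 3, length.out = n),
    heart_rate = seq(100, by = 10, length.out = n),
    temperature_c = rep(c(36.5, 38.2), length.out = n),
    muac_mm = seq(100, by = 10, length.out = n),
    spo2 = rep(c(98, 92), length.out = n),
    parent_concern = rep(c(0, 1), length.out = n),
    difficulty_breathing = rep(c(1, 0), length.out = n),
    oedema = rep(0, n),
    pallor = rep(c(0, 0, 1), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    site = rep("siteA", n),
    admitted = rep(c(1, 0), length.out = n),
    los_hours = ifelse(rep(c(1, 0), length.out = n) == 1, 36, NA_real_),
    readmit_48h = rep(0, n),
    readmit_late = rep(0, n),
    died = rep(0, n)
  )
}

# Published-style stratification counts: under-5 table at thresholds
# (0.08, 0.40) and neonatal table at (0.13, 0.41).
under5_counts <- function() {
  list(n_total = c(6018, 4384, 1193), n_endpoint = c(151, 415, 471),
       thresholds = threshold_pair(0.08, 0.40, "published under-5 table"))
}

neonatal_counts <- function() {
  list(n_total = c(178, 192, 113), n_endpoint = c(12, 43, 77),
       thresholds = threshold_pair(0.13, 0.41, "published neonatal table"))
}

# Scores/outcomes engineered so that stratification_table() reproduces the
# given category counts exactly (one constant score per category).
counts_to_scores <- function(counts) {
  mid <- c(mean(c(0, counts$thresholds$low)),
           mean(c(counts$thresholds$low, counts$thresholds$high)),
           mean(c(counts$thresholds$high, 1)))
  scores <- rep(mid, counts$n_total)
  outcomes <- unlist(lapply(1:3, function(i) {
    c(rep(1, counts$n_endpoint[i]), rep(0, counts$n_total[i] - counts$n_endpoint[i]))
  }))
  list(scores = scores, outcomes = outcomes, thresholds = counts$thresholds)
}

# Brute-force AUROC over all case/non-case pairs (ties count one half).
auc_pairs <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p-value by exhaustive hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A neonatal simulation configuration around the printed updated equation.
neonatal_sim_config <- function(n, seed, site_effects = c(siteA = 0),
                                missingness_rate = 0) {
  sim_config(
    n = n, seed = seed,
    true_coefficients = neonatal_model(),
    age_weights = c("<1m" = 1, "1-2m" = 0, ">2-6m" = 0, ">6m-<5y" = 0),
    site_effects = site_effects,
    missingness_rate = missingness_rate,
    binary_prevalence = c(parent_concern = 0.25, difficulty_breathing = 0.20,
                          oedema = 0.01, pallor = 0.10),
    predictor_means = list(temperature_c = function(age) rep(36.8, length(age)))
  )
}
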