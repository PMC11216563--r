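# Shared internal helpers.

# Numerically stable inverse logit: exact 0/1 for extreme inputs instead of
# NaN from exp() overflow.
inv_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos & !is.na(x)])
  out[!pos & !is.na(x)] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

logit <- function(p) log(p) - log1p(-p)

# Clamp probabilities away from {0,1} before logit-based fits.
clamp_prob <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)

assert_prob_vector <- function(x, name = "scores") {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector without missing values.", name))
  }
  if (any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

assert_binary_vector <- function(y, name = "outcomes") {
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort(sprintf("`%s` must be 0/1 with no missing values.", name))
  }
  invisible(y)
}

assert_same_length <- function(x, y, xname = "scores", yname = "outcomes") {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` (%d) and `%s` (%d) must have equal length.",
                  xname, length(x), yname, length(y)))
  }
  invisible(TRUE)
}

# Deterministic per-record seed stream: record i always gets the same seed for
# a given master seed, so growing n never reshuffles earlier records.
record_seeds <- function(master_seed, n) {
  (as.double(master_seed) %% 2147483647 + seq_len(n) * 2654435761) %% 2147483647
}

# The nine predictor columns, in canonical order.
predictor_columns <- function() {
  c("age_months", "heart_rate", "temperature_c", "muac_mm", "spo2",
    "parent_concern", "difficulty_breathing", "oedema", "pallor")
}

continuous_predictors <- function() {
  c("age_months", "heart_rate", "temperature_c", "muac_mm", "spo2")
}

binary_predictors <- function() {
  c("parent_concern", "difficulty_breathing", "oedema", "pallor")
}

outcome_columns <- function() {
  c("admitted", "los_hours", "readmit_48h", "readmit_late", "died")
}
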