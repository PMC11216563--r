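#' Maximum-likelihood logistic regression with offset support
#'
#' A small iteratively-reweighted-least-squares (IRLS) fitter used by the
#' calibration metrics and the model-update cascade. It supports an offset
#' term (needed for recalibration-in-the-large, where the original linear
#' predictor is kept fixed) and intercept-only designs, and reports
#' convergence and separation diagnostics instead of silently returning
#' diverging coefficients.
#'
#' Convergence: maximum absolute coefficient change below `tol`
#' (default 1e-8) within `max_iter` iterations (default 100). Suspected
#' perfect separation (coefficient max-norm exceeding 1e3 while steps remain
#' non-vanishing) stops the iteration with `converged = FALSE` and
#' `separation = TRUE`.
#'
#' @param x Predictor matrix (columns are predictors, no intercept column),
#'   or `NULL` for an intercept-only fit.
#' @param y 0/1 outcome vector.
#' @param offset Optional per-record offset added to the linear predictor.
#' @param intercept Include an intercept? (default `TRUE`).
#' @param tol,max_iter IRLS stopping controls.
#' @return An object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `log_likelihood`, `converged`, `separation`,
#'   `n_iterations`, `offset_used`, `fitted`, `n`.
#' @export
fit_logistic <- function(x = NULL, y, offset = NULL, intercept = TRUE,
                         tol = 1e-8, max_iter = 100L) {
  assert_binary_vector(y)
  n <- length(y)
  X <- if (is.null(x)) matrix(numeric(0), nrow = n, ncol = 0) else as.matrix(x)
  if (nrow(X) != n) abort("`x` and `y` must have the same number of rows.")
  if (anyNA(X)) abort("`x` must have no missing cells.")
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (ncol(X) == 0) abort("Nothing to fit: no predictors and no intercept.")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(X)[colnames(X) == ""] <-
    paste0("x", which(colnames(X) == ""))
  p <- ncol(X)
  if (n <= p) abort("More parameters than observations.")
  off <- if (is.null(offset)) numeric(n) else as.numeric(offset)

  beta <- numeric(p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- off + drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X
    step <- tryCatch(solve(H, XtW %*% z), error = function(e) NULL)
    if (is.null(step)) {
      if (iter == 1L) {
        abort(paste0("IRLS normal equations are singular ",
                     "(collinear design)."))
      }
      # weights collapsed mid-fit: quasi-separation, keep current estimate
      separation <- TRUE
      break
    }
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 1e3 && max(abs(step)) > 1e-4) {
      separation <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  eta <- off + drop(X %*% beta)
  mu <- inv_logit(eta)
  if (!converged) {
    # classify the failure: fitted classes pulled to 0/1 (full separation) or
    # a diverging predictor coefficient (quasi-separation on one column)
    slopes <- beta[colnames(X) != "(Intercept)"]
    if (separation ||
        (all(mu[y == 1] > 1 - 1e-4) && all(mu[y == 0] < 1e-4)) ||
        (length(slopes) > 0 && any(abs(slopes) > 15))) {
      separation <- TRUE
      warn("Suspected perfect separation: coefficients diverging; fit flagged.")
    } else {
      warn(sprintf("IRLS did not converge in %d iterations.", max_iter))
    }
  }
  mu_c <- clamp_prob(mu)
  ll <- sum(y * log(mu_c) + (1 - y) * log1p(-mu_c))
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(diag(cov))
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      standard_errors = setNames(se, colnames(X)),
      log_likelihood = ll,
      converged = converged,
      separation = separation,
      n_iterations = iter,
      offset_used = !is.null(offset),
      fitted = mu,
      n = n
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %d obs, logLik %.3f, %s in %d iterations%s>\n",
              x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (x$separation) ", separation suspected" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @exportS3Method
tidy.logistic_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(x$coefficients / x$standard_errors),
    conf.low = unname(x$coefficients - z * x$standard_errors),
    conf.high = unname(x$coefficients + z * x$standard_errors)
  )
}

#' @exportS3Method
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    nobs = x$n,
    converged = x$converged,
    separation = x$separation,
    n_iterations = x$n_iterations,
    offset_used = x$offset_used
  )
}
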