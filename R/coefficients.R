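#' Create a triage-model coefficient set
#'
#' A coefficient set holds the intercept, the nine named predictor
#' coefficients and the transform flags of a logistic triage model, and is the
#' object consumed by [predict_risk()], [run_update_cascade()] and
#' [revise_model()].
#'
#' The nine predictors are: age (entered either raw or as its square root),
#' heart rate (beats/min), temperature (deg C), mid-upper arm circumference
#' (MUAC, mm by default), oxygen saturation (entered via the virtual-shunt
#' transform or raw), parental concern, difficulty breathing, oedema and
#' pallor (binary signs).
#'
#' @param intercept Model intercept on the logit scale.
#' @param coefficients Named numeric vector with exactly the nine predictor
#'   names returned by `predictor_names()`.
#' @param age_transform `"sqrt"` (the model uses the square root of age in
#'   months) or `"identity"`.
#' @param spo2_transform An [spo2_transform_spec()], controlling how oxygen
#'   saturation enters the linear predictor.
#' @param muac_unit Unit the MUAC coefficient expects; recorded and echoed in
#'   reports because the coefficient magnitude is unit-dependent.
#' @param label Free-text provenance label.
#'
#' @return An object of class `coefficient_set`.
#' @seealso [neonatal_model()], [synthetic_under5_model()],
#'   [read_coefficient_set()]
#' @export
coefficient_set <- function(intercept,
                            coefficients,
                            age_transform = c("sqrt", "identity"),
                            spo2_transform = spo2_transform_spec(),
                            muac_unit = "mm",
                            label = "unlabelled") {
  age_transform <- match.arg(age_transform)
  required <- predictor_names()
  if (is.null(names(coefficients)) || !setequal(names(coefficients), required) ||
      length(coefficients) != 9L) {
    abort(paste0("`coefficients` must be a named vector with exactly the nine ",
                 "predictor names: ", paste(required, collapse = ", ")))
  }
  structure(
    list(
      intercept = as.numeric(intercept),
      coefficients = as.numeric(coefficients[required]) |> setNames(required),
      age_transform = age_transform,
      spo2_transform = spo2_transform,
      muac_unit = muac_unit,
      label = label
    ),
    class = "coefficient_set"
  )
}

#' Canonical predictor names of the nine-predictor triage model
#'
#' @return Character vector of length nine.
#' @export
predictor_names <- function() {
  c("age", "heart_rate", "temperature", "muac", "transformed_spo2",
    "parent_concern", "difficulty_breathing", "oedema", "pallor")
}

#' Oxygen-saturation transform specification
#'
#' The virtual-shunt transform maps SpO2 (%) to an equivalent pulmonary shunt
#' fraction, linearizing oxygen-saturation severity; it is monotone
#' non-increasing in SpO2. The default constants give
#' `a * log10(b - spo2) + c` with `a = 68.864`, `b = 103.711`,
#' `c = -52.109`; all three are configurable. SpO2 values at or above the
#' asymptote `b` are clamped to `b - epsilon`.
#'
#' @param kind `"virtual_shunt"` or `"identity"`.
#' @param a,b,c Constants of the virtual-shunt formula.
#' @param epsilon Clamping margin below the asymptote.
#'
#' @return An object of class `spo2_transform_spec`.
#' @export
spo2_transform_spec <- function(kind = c("virtual_shunt", "identity"),
                                a = 68.864, b = 103.711, c = -52.109,
                                epsilon = 0.1) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, a = a, b = b, c = c, epsilon = epsilon),
    class = "spo2_transform_spec"
  )
}

#' The updated neonatal triage model
#'
#' The revised nine-predictor equation for neonates (age under one month):
#' `logit(p) = -21.847 - 3.415*sqrt(age) - 0.013*heart_rate +
#' 0.674*temperature - 0.011*muac + 0.048*transformed_spo2 +
#' 3.135*parent_concern + 0.216*difficulty_breathing - 3.332*oedema +
#' 1.588*pallor`, with age in months and MUAC in millimetres.
#'
#' @return A [coefficient_set()].
#' @export
neonatal_model <- function() {
  coefficient_set(
    intercept = -21.847,
    coefficients = c(
      age = -3.415,
      heart_rate = -0.013,
      temperature = 0.674,
      muac = -0.011,
      transformed_spo2 = 0.048,
      parent_concern = 3.135,
      difficulty_breathing = 0.216,
      oedema = -3.332,
      pallor = 1.588
    ),
    age_transform = "sqrt",
    spo2_transform = spo2_transform_spec(),
    label = "updated neonatal model"
  )
}

#' A synthetic under-5 "truth" coefficient set
#'
#' A plausible nine-predictor logistic model used as the default data
#' generating truth by [generate_cohort()] for under-5 cohorts. It is
#' synthetic: the coefficients were chosen so that, under the generator's
#' default predictor distributions, the overall event rate is roughly 9% and
#' risk falls with age and oxygen saturation and rises with temperature and
#' the danger signs. It is not a published model and must not be used to score
#' real patients.
#'
#' @return A [coefficient_set()].
#' @export
synthetic_under5_model <- function() {
  coefficient_set(
    intercept = -20.5,
    coefficients = c(
      age = -0.15,
      heart_rate = 0.015,
      temperature = 0.5,
      muac = -0.02,
      transformed_spo2 = 0.05,
      parent_concern = 1.0,
      difficulty_breathing = 0.7,
      oedema = 1.5,
      pallor = 1.0
    ),
    age_transform = "sqrt",
    spo2_transform = spo2_transform_spec(),
    label = "synthetic under-5 truth (simulation only)"
  )
}

#' Read / write a coefficient set
#'
#' Coefficient sets are serialized as small JSON files (name-value pairs plus
#' transform flags), so models can be exchanged between runs and sites.
#'
#' @param path File path.
#' @param x A [coefficient_set()].
#' @return `read_coefficient_set()` returns a [coefficient_set()];
#'   `write_coefficient_set()` returns `path` invisibly.
#' @export
read_coefficient_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("Coefficient file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- raw$spo2_transform
  coefficient_set(
    intercept = raw$intercept,
    coefficients = unlist(raw$coefficients),
    age_transform = raw$age_transform,
    spo2_transform = spo2_transform_spec(
      kind = spec$kind, a = spec$a, b = spec$b, c = spec$c,
      epsilon = spec$epsilon
    ),
    muac_unit = raw$muac_unit %||% "mm",
    label = raw$label %||% basename(path)
  )
}

#' @rdname read_coefficient_set
#' @export
write_coefficient_set <- function(x, path) {
  stopifnot(inherits(x, "coefficient_set"))
  jsonlite::write_json(
    list(
      intercept = x$intercept,
      coefficients = as.list(x$coefficients),
      age_transform = x$age_transform,
      spo2_transform = unclass(x$spo2_transform),
      muac_unit = x$muac_unit,
      label = x$label
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set: %s>\n", x$label))
  cat(sprintf("  intercept: %.4g | age: %s | spo2: %s | muac unit: %s\n",
              x$intercept, x$age_transform, x$spo2_transform$kind, x$muac_unit))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @exportS3Method
tidy.coefficient_set <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}
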