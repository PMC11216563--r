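#' Age transform used by the triage model
#'
#' The triage model enters age through its square root to linearize the
#' nonlinear age-risk relationship; the identity mode is used by revised
#' models fitted on narrow age ranges.
#'
#' @param age Age in months, non-negative.
#' @param mode `"sqrt"` or `"identity"`.
#' @return Transformed age, same length as `age`.
#' @export
transform_age <- function(age, mode = c("sqrt", "identity")) {
  mode <- match.arg(mode)
  if (any(age < 0, na.rm = TRUE)) abort("`age` must be non-negative (months).")
  if (mode == "sqrt") sqrt(age) else age
}

#' Oxygen-saturation transform (virtual shunt)
#'
#' Maps SpO2 (%) to the model's transformed oxygen saturation. The virtual
#' shunt expresses low saturation as an equivalent pulmonary shunt fraction,
#' `a * log10(b - spo2) + c`; it is monotone non-increasing in SpO2 so lower
#' saturations yield larger (more severe) values. SpO2 at or above the
#' asymptote `b` is clamped to `b - epsilon`.
#'
#' @param spo2 Oxygen saturation in percent, in (0, 100].
#' @param spec An [spo2_transform_spec()].
#' @return Transformed SpO2, same length as `spo2`.
#' @export
transform_spo2 <- function(spo2, spec = spo2_transform_spec()) {
  stopifnot(inherits(spec, "spo2_transform_spec"))
  if (any(spo2 <= 0, na.rm = TRUE)) abort("`spo2` must be positive (percent).")
  if (any(spo2 > 100, na.rm = TRUE)) abort("`spo2` must be at most 100 (percent).")
  if (spec$kind == "identity") return(spo2)
  s <- pmin(spo2, spec$b - spec$epsilon)
  spec$a * log10(spec$b - s) + spec$c
}
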