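#' Operating condition of the liquid-solid system
#'
#' A condition is a (temperature, ethanol) operating point of the model wine
#' system. Temperatures are given in degrees Celsius at every user-facing
#' interface and converted to Kelvin internally; ethanol is percent by volume.
#'
#' The parameter surfaces were calibrated on adsorption experiments spanning
#' 15-35 degrees C and 0-15 % v/v ethanol. Conditions outside that envelope
#' are permitted but carry an `extrapolated` flag, since the rational surfaces
#' have no physical support (and, for the equilibrium-constant surface, a pole
#' close to the high-temperature, high-ethanol corner) outside it.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @param ethanol_pct ethanol concentration, % v/v (>= 0).
#' @return An object of class `"pa_condition"` with fields `temperature_C`,
#'   `temperature_K`, `ethanol_pct` and logical `extrapolated`.
#' @examples
#' condition(35, 15)
#' condition(40, 15)$extrapolated  # outside the calibrated envelope
#' @export
condition <- function(temperature_C, ethanol_pct) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(ethanol_pct), length(ethanol_pct) == 1L)
  temperature_K <- temperature_C + 273.15
  if (temperature_K <= 0) {
    stop("absolute temperature must be positive (got ", temperature_K, " K)")
  }
  if (ethanol_pct < 0) {
    stop("ethanol_pct must be non-negative")
  }
  extrapolated <- temperature_C < 15 || temperature_C > 35 ||
    ethanol_pct > 15
  structure(
    list(temperature_C = temperature_C,
         temperature_K = temperature_K,
         ethanol_pct = ethanol_pct,
         extrapolated = extrapolated),
    class = "pa_condition"
  )
}

#' @export
print.pa_condition <- function(x, ...) {
  cat(sprintf("Condition: %.2f degC (%.2f K), %.1f %% v/v ethanol%s\n",
              x$temperature_C, x$temperature_K, x$ethanol_pct,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Rational parameter surface in temperature and ethanol
#'
#' Both Langmuir parameters are modelled as rational functions of absolute
#' temperature T (Kelvin) and ethanol E (% v/v):
#'
#' \deqn{f(T, E) = \frac{n_0 + n_T T + n_E E}{d_0 + d_T T + d_E E + d_{TE} T E}}
#'
#' @param numerator named numeric vector with elements `const`, `coef_T`,
#'   `coef_E` (missing elements default to 0).
#' @param denominator named numeric vector with elements `const`, `coef_T`,
#'   `coef_E`, `coef_TE` (missing elements default to 0).
#' @param label surface label, e.g. `"keq"` or `"scwm"`.
#' @return An object of class `"rational_surface"`.
#' @seealso [surface_coefficients()] for the shipped coefficient sets.
#' @export
rational_surface <- function(numerator, denominator, label = "surface") {
  num <- c(const = 0, coef_T = 0, coef_E = 0)
  den <- c(const = 0, coef_T = 0, coef_E = 0, coef_TE = 0)
  bad <- setdiff(names(numerator), names(num))
  if (length(bad)) stop("unknown numerator coefficient: ", bad[1])
  bad <- setdiff(names(denominator), names(den))
  if (length(bad)) stop("unknown denominator coefficient: ", bad[1])
  num[names(numerator)] <- numerator
  den[names(denominator)] <- denominator
  if (all(den == 0)) stop("denominator has no nonzero coefficient")
  structure(list(numerator = num, denominator = den, label = label),
            class = "rational_surface")
}

#' Shipped coefficient sets for the Keq and SCWM surfaces
#'
#' Two coefficient sets are available:
#'
#' * `"default"` - the transcription used throughout this package. Relative
#'   to the typeset source two superscript exponent signs are restored (the
#'   temperature coefficient of the Keq numerator and the constant of the
#'   SCWM numerator); with them both surfaces are strictly positive over the
#'   calibrated envelope and the batch solver reproduces the published
#'   winemaking extrapolation (approximately 525 mg model-predicted loss and
#'   758 mg cold-soak loss per litre).
#' * `"printed"` - the coefficients exactly as typeset. At zero ethanol this
#'   set collapses the saturation surface to 1/T mg/mg, which contradicts the
#'   measured adsorption capacities; it is retained for traceability and for
#'   users who wish to supply their own corrections.
#'
#' Either set can be overridden wholesale by constructing surfaces with
#' [rational_surface()] or via the `model.coefficients` config block.
#'
#' @param set `"default"` or `"printed"`.
#' @return A list with elements `keq` and `scwm`, each a
#'   [rational_surface()]. `keq` is in L per mg PA (catechin units); `scwm`
#'   in mg PA per mg CWM.
#' @examples
#' cs <- surface_coefficients()
#' evaluate_surface(cs$keq, condition(35, 15))
#' @export
surface_coefficients <- function(set = c("default", "printed")) {
  set <- match.arg(set)
  keq_num_T <- if (set == "default") -2.69e3 else -2.69e-3
  scwm_num_const <- if (set == "default") 4.57e1 else 4.57e-1
  list(
    keq = rational_surface(
      numerator = c(const = 1.21e-3, coef_T = keq_num_T),
      denominator = c(coef_T = -9.01, coef_E = -1.25e2, coef_TE = 1),
      label = "keq"
    ),
    scwm = rational_surface(
      numerator = c(const = scwm_num_const, coef_E = 2.04e1),
      denominator = c(coef_E = -6.69, coef_T = 4.57e-1, coef_TE = 1),
      label = "scwm"
    )
  )
}

#' Evaluate a rational parameter surface at a condition
#'
#' @param coeffs a [rational_surface()].
#' @param cond a [condition()].
#' @param tol denominators smaller than `tol` in absolute value are treated
#'   as singular.
#' @return The scalar surface value.
#' @export
evaluate_surface <- function(coeffs, cond, tol = 1e-12) {
  stopifnot(inherits(coeffs, "rational_surface"), inherits(cond, "pa_condition"))
  T <- cond$temperature_K
  E <- cond$ethanol_pct
  num <- coeffs$numerator
  den <- coeffs$denominator
  d <- den[["const"]] + den[["coef_T"]] * T + den[["coef_E"]] * E +
    den[["coef_TE"]] * T * E
  if (abs(d) < tol) {
    stop(sprintf(
      "surface '%s' is singular at %.2f degC, %.1f %% ethanol (denominator %.3e)",
      coeffs$label, cond$temperature_C, E, d))
  }
  n <- num[["const"]] + num[["coef_T"]] * T + num[["coef_E"]] * E
  n / d
}

#' Langmuir parameters at an operating condition
#'
#' Evaluates the equilibrium-constant and saturation-capacity surfaces at a
#' condition and packages the pair for the isotherm and batch solver. A
#' non-positive surface value means the adsorption model is not physically
#' meaningful at that condition and raises an error.
#'
#' @param cond a [condition()].
#' @param coefficients list with `keq` and `scwm` surfaces, as returned by
#'   [surface_coefficients()].
#' @return Object of class `"langmuir_parameters"`: `keq` (L/mg PA C.U.),
#'   `scwm` (mg PA C.U./mg CWM), the `condition`, and `extrapolated`.
#' @examples
#' langmuir_parameters(condition(35, 15))
#' @export
langmuir_parameters <- function(cond, coefficients = surface_coefficients()) {
  stopifnot(inherits(cond, "pa_condition"))
  keq <- evaluate_surface(coefficients$keq, cond)
  scwm <- evaluate_surface(coefficients$scwm, cond)
  if (keq <= 0 || scwm <= 0) {
    stop(sprintf(
      paste0("non-positive Langmuir parameter at %.2f degC, %.1f %% ethanol ",
             "(Keq = %.4g, SCWM = %.4g): model not physically meaningful there"),
      cond$temperature_C, cond$ethanol_pct, keq, scwm))
  }
  if (cond$extrapolated) {
    warning(sprintf(
      "condition %.2f degC, %.1f %% ethanol is outside the calibrated envelope (15-35 degC, 0-15 %%)",
      cond$temperature_C, cond$ethanol_pct))
  }
  structure(list(keq = keq, scwm = scwm, condition = cond,
                 extrapolated = cond$extrapolated),
            class = "langmuir_parameters")
}

#' Construct Langmuir parameters directly from known constants
#'
#' @param keq equilibrium constant, L per mg PA (C.U.); must be positive.
#' @param scwm saturation capacity, mg PA (C.U.) per mg CWM; must be positive.
#' @return Object of class `"langmuir_parameters"`.
#' @export
langmuir_constants <- function(keq, scwm) {
  stopifnot(is.numeric(keq), is.numeric(scwm), length(keq) == 1L,
            length(scwm) == 1L)
  if (keq <= 0 || scwm <= 0) stop("keq and scwm must be positive")
  structure(list(keq = keq, scwm = scwm, condition = NULL,
                 extrapolated = FALSE),
            class = "langmuir_parameters")
}

#' @export
print.langmuir_parameters <- function(x, ...) {
  cat(sprintf("Langmuir parameters: Keq = %.4g L/mg, SCWM = %.4g mg/mg\n",
              x$keq, x$scwm))
  if (!is.null(x$condition)) print(x$condition)
  invisible(x)
}
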