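#' Ferric chloride assay calibration
#'
#' Calibration of the 510 nm iron-reactive phenolics assay against a
#' (+)-catechin standard series; all PA concentrations carried by the package
#' are therefore in mg catechin units (C.U.) per L.
#'
#' On the bench, 75 uL of sample are mixed with 800 uL of resuspension
#' buffer; a background read is taken at 875 uL total, then 125 uL of ferric
#' chloride reagent are added and the final read is taken at 1000 uL. The
#' default `dilution_factor` of 1000/75 maps cuvette concentration at the
#' final read back to sample concentration, and the default
#' `background_scale` of 875/1000 rescales the background absorbance to the
#' final-read volume before subtraction.
#'
#' @param slope absorbance per (mg C.U./L) at cuvette concentration; > 0.
#' @param intercept absorbance at zero concentration.
#' @param dilution_factor sample-to-cuvette dilution, >= 1.
#' @param background_scale factor applied to the background read before
#'   subtraction from the final read.
#' @param r_squared optional fit quality carried from [build_calibration()].
#' @return Object of class `"assay_calibration"`.
#' @export
assay_calibration <- function(slope, intercept = 0,
                              dilution_factor = 1000 / 75,
                              background_scale = 875 / 1000,
                              r_squared = NA_real_) {
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be positive")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  structure(list(slope = slope, intercept = intercept,
                 dilution_factor = dilution_factor,
                 background_scale = background_scale,
                 r_squared = r_squared),
            class = "assay_calibration")
}

#' Build an assay calibration from standards
#'
#' Ordinary least-squares line through `(concentration, absorbance)`
#' standards.
#'
#' @param standards data frame with columns `conc_mg_per_L` and `absorbance`
#'   (the `calibration.csv` schema), or a two-column data frame.
#' @inheritParams assay_calibration
#' @return An [assay_calibration()] with `r_squared` filled in.
#' @examples
#' std <- data.frame(conc_mg_per_L = c(0, 100), absorbance = c(0, 0.1))
#' build_calibration(std)
#' @export
build_calibration <- function(standards, dilution_factor = 1000 / 75,
                              background_scale = 875 / 1000) {
  standards <- as.data.frame(standards)
  if (!all(c("conc_mg_per_L", "absorbance") %in% names(standards))) {
    names(standards)[1:2] <- c("conc_mg_per_L", "absorbance")
  }
  if (nrow(standards) < 2L || length(unique(standards$conc_mg_per_L)) < 2L) {
    stop("singular calibration design: need at least two distinct concentrations")
  }
  fit <- stats::lm(absorbance ~ conc_mg_per_L, data = standards)
  r2 <- summary(fit)$r.squared
  assay_calibration(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    dilution_factor = dilution_factor,
                    background_scale = background_scale,
                    r_squared = r2)
}

#' Concentration from assay absorbance readings
#'
#' Inverts the calibration line after a volume-consistent background
#' subtraction:
#' \deqn{C = d \cdot \frac{(A_{final} - s\,A_{background}) - b}{a}}
#' with dilution factor `d`, background scale `s`, slope `a` and intercept
#' `b`. Negative results are floored at zero with a warning (expected from
#' noise near blank).
#'
#' @param a_final absorbance at 510 nm after reagent addition (vectorised).
#' @param cal an [assay_calibration()].
#' @param a_background absorbance before reagent addition (default 0).
#' @return Concentration(s), mg C.U./L.
#' @examples
#' cal <- assay_calibration(slope = 0.001, dilution_factor = 1)
#' concentration_from_absorbance(0.5, cal)
#' @export
concentration_from_absorbance <- function(a_final, cal, a_background = 0) {
  stopifnot(inherits(cal, "assay_calibration"))
  if (any(!is.finite(a_final)) || any(!is.finite(a_background))) {
    stop("absorbance readings must be finite")
  }
  conc <- cal$dilution_factor *
    ((a_final - cal$background_scale * a_background) - cal$intercept) /
    cal$slope
  if (any(conc < -1e-8)) {
    warning(sum(conc < -1e-8), " negative concentration(s) floored at 0")
  }
  pmax(conc, 0)
}

#' Synthetic absorbance for a known concentration
#'
#' Exact inverse of [concentration_from_absorbance()]; used by the synthetic
#' data generator so that the quantification chain round-trips the truth at
#' zero noise.
#'
#' @param conc_mg_per_L concentration(s), mg C.U./L.
#' @param cal an [assay_calibration()].
#' @param a_background background absorbance(s) to fold in.
#' @return Final-read absorbance(s).
#' @export
absorbance_from_concentration <- function(conc_mg_per_L, cal, a_background = 0) {
  stopifnot(inherits(cal, "assay_calibration"))
  cal$slope * conc_mg_per_L / cal$dilution_factor + cal$intercept +
    cal$background_scale * a_background
}

#' Adsorbed PA per mg of cell wall material
#'
#' The adsorbed amount is inferred from the concentration difference between
#' the CWM-free controls and the trial: \eqn{q = (\bar{C}_{control} -
#' C_{trial}) V / m}. A negative result (trial above control) is physically a
#' net release and is reported as-is with a warning.
#'
#' @param control_mean mean control concentration, mg C.U./L.
#' @param trial trial concentration(s), mg C.U./L.
#' @param volume_L solution volume, L.
#' @param cwm_mass_mg CWM mass, mg; must be positive.
#' @return Adsorbed amount(s), mg PA/mg CWM.
#' @examples
#' adsorbed_per_mg(1500, 900, volume_L = 0.0045, cwm_mass_mg = 10)
#' @export
adsorbed_per_mg <- function(control_mean, trial, volume_L, cwm_mass_mg) {
  if (!is.finite(cwm_mass_mg) || cwm_mass_mg <= 0) {
    stop("cwm_mass_mg must be positive to express adsorption per mg CWM")
  }
  q <- (control_mean - trial) * volume_L / cwm_mass_mg
  if (any(q < 0)) {
    warning(sum(q < 0), " trial concentration(s) above control: negative adsorption reported")
  }
  q
}
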