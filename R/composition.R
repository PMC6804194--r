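#' Molecular weights of flavan-3-ol subunits
#'
#' Free flavan-3-ol masses, g/mol. Interflavan-bond and phloroglucinol
#' adduct mass corrections are deliberately not applied (see the methods
#' vignette); supply a modified table to change the convention.
#' @return Named numeric vector.
#' @export
subunit_mw_table <- function() {
  c(catechin = 290.27,
    epicatechin = 290.27,
    `epicatechin-gallate` = 442.37,
    epigallocatechin = 306.27)
}

#' Phloroglucinolysis subunit profile
#'
#' Acid-catalysed depolymerisation in the presence of phloroglucinol
#' releases terminal subunits as free flavan-3-ols and converts extension
#' subunits to phloroglucinol adducts; the molar amounts of each species at
#' each position determine the polymer's mean degree of polymerization and
#' composition.
#'
#' @param data data frame with columns `species` (one of `catechin`,
#'   `epicatechin`, `epicatechin-gallate`, `epigallocatechin`), `position`
#'   (`terminal` or `extension`) and `nmol` (>= 0). The `subunits.csv`
#'   schema.
#' @param mw named molecular weight table, g/mol.
#' @return Object of class `"subunit_profile"`.
#' @export
subunit_profile <- function(data, mw = subunit_mw_table()) {
  data <- as.data.frame(data)
  needed <- c("species", "position", "nmol")
  if (!all(needed %in% names(data))) {
    stop("subunit data must have columns ", paste(needed, collapse = ", "))
  }
  bad <- setdiff(unique(data$species), names(mw))
  if (length(bad)) stop("unknown subunit species: ", paste(bad, collapse = ", "))
  if (!all(data$position %in% c("terminal", "extension"))) {
    stop("position must be 'terminal' or 'extension'")
  }
  if (any(data$nmol < 0)) stop("subunit amounts must be non-negative")
  if (sum(data$nmol) <= 0) stop("empty subunit profile")
  structure(list(data = tibble::as_tibble(data), mw = mw),
            class = "subunit_profile")
}

profile_moles <- function(profile, species = NULL, position = NULL) {
  d <- profile$data
  if (!is.null(species)) d <- d[d$species %in% species, ]
  if (!is.null(position)) d <- d[d$position == position, ]
  sum(d$nmol)
}

#' Mean degree of polymerization
#'
#' Total subunit moles divided by terminal subunit moles: the average chain
#' length implied by the ratio of free monomers to phloroglucinol adducts.
#'
#' @param profile a [subunit_profile()].
#' @return Dimensionless mDP, >= 1.
#' @examples
#' p <- subunit_profile(data.frame(
#'   species = c("catechin", "epicatechin"),
#'   position = c("terminal", "extension"),
#'   nmol = c(1, 3)))
#' mdp(p)  # 4
#' @export
mdp <- function(profile) {
  stopifnot(inherits(profile, "subunit_profile"))
  terminal <- profile_moles(profile, position = "terminal")
  if (terminal <= 0) stop("undefined mDP: no terminal subunits")
  profile_moles(profile) / terminal
}

#' Percent galloylation
#'
#' Share of subunits carrying a gallate ester group (epicatechin gallate),
#' as a molar percentage of all subunits.
#'
#' @param profile a [subunit_profile()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_galloylation <- function(profile) {
  stopifnot(inherits(profile, "subunit_profile"))
  100 * profile_moles(profile, species = "epicatechin-gallate") /
    profile_moles(profile)
}

#' Percent gallo units
#'
#' Share of subunits with a trihydroxylated B-ring (epigallocatechin), a
#' marker of skin-derived proanthocyanidin, as a molar percentage of all
#' subunits.
#'
#' @param profile a [subunit_profile()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_gallo <- function(profile) {
  stopifnot(inherits(profile, "subunit_profile"))
  100 * profile_moles(profile, species = "epigallocatechin") /
    profile_moles(profile)
}

#' Average molecular weight of the polymer
#'
#' mDP times the mole-fraction-weighted subunit mass: the expected mass of a
#' polymer chain given the subunit pool and the average chain length.
#'
#' @param profile a [subunit_profile()].
#' @return g/mol.
#' @export
average_mw <- function(profile) {
  stopifnot(inherits(profile, "subunit_profile"))
  d <- profile$data
  total <- sum(d$nmol)
  mean_mw <- sum(d$nmol * profile$mw[d$species]) / total
  mdp(profile) * mean_mw
}

#' Gel permeation chromatography trace
#'
#' An ordered elution profile with a calibration mapping elution volume to
#' log10 molar mass. GPC separates by size, so the calibration must be
#' monotone decreasing in elution volume (large molecules elute first).
#'
#' @param elution_mL elution volumes, mL, strictly increasing.
#' @param signal detector signal (mass-proportional), >= 0.
#' @param calibration data frame with columns `elution_mL` and `log10_mw`
#'   (the `gpc_cal.csv` schema), monotone decreasing in `log10_mw`.
#' @return Object of class `"gpc_trace"`.
#' @export
gpc_trace <- function(elution_mL, signal, calibration) {
  stopifnot(length(elution_mL) == length(signal), length(elution_mL) >= 1L)
  if (any(signal < 0)) stop("GPC signal must be non-negative")
  if (any(diff(elution_mL) <= 0)) stop("elution volumes must be strictly increasing")
  calibration <- as.data.frame(calibration)
  if (!all(c("elution_mL", "log10_mw") %in% names(calibration))) {
    stop("calibration must have columns elution_mL, log10_mw")
  }
  calibration <- calibration[order(calibration$elution_mL), ]
  if (any(diff(calibration$log10_mw) >= 0)) {
    stop("GPC calibration must be monotone decreasing in elution volume")
  }
  structure(list(elution_mL = elution_mL, signal = signal,
                 calibration = calibration),
            class = "gpc_trace")
}

#' Molar mass at a cumulative mass quantile
#'
#' Maps the trace through the calibration to (molar mass, mass) pairs,
#' accumulates mass from low to high molar mass, and returns the molar mass
#' at which the cumulative mass fraction first reaches the quantile (with
#' linear interpolation between samples). With the low-to-high convention a
#' 0.90 quantile characterises the high-molar-mass tail of the polymer
#' population.
#'
#' @param trace a [gpc_trace()].
#' @param quantile mass quantile in (0, 1); default 0.9.
#' @return Molar mass, g/mol.
#' @export
molar_mass_at_quantile <- function(trace, quantile = 0.9) {
  stopifnot(inherits(trace, "gpc_trace"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (all(trace$signal == 0)) stop("all-zero GPC signal")
  cal <- trace$calibration
  log10_mw <- stats::approx(cal$elution_mL, cal$log10_mw,
                            xout = trace$elution_mL, rule = 2)$y
  mw <- 10^log10_mw
  ord <- order(mw)
  mw <- mw[ord]
  mass <- trace$signal[ord]
  # zero-mass samples carry no information; dropping them keeps a point mass
  # at a single molar mass from being smeared across the adjacent grid cell
  keep <- mass > 0
  mw <- mw[keep]
  mass <- mass[keep]
  cum <- cumsum(mass) / sum(mass)
  i <- which(cum >= quantile)[1]
  if (i == 1L) return(mw[1])
  prev <- cum[i - 1L]
  if (cum[i] == prev) return(mw[i])
  mw[i - 1L] + (quantile - prev) / (cum[i] - prev) * (mw[i] - mw[i - 1L])
}
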