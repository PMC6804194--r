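#' Multiplicative assay noise model
#'
#' Noise is multiplicative Gaussian on concentration by default (the bench
#' replicate scatter grows with the mean), with the coefficient of variation
#' sized to the bench study's replicate standard deviations (CV roughly
#' 1-10 %). Placement on absorbance instead is available where generators
#' accept `noise_on`.
#'
#' @param cv coefficient of variation, >= 0 (default 0.03).
#' @param replicates number of replicates (default 3, as on the bench).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(cv = 0.03, replicates = 3, seed = NULL) {
  if (cv < 0) stop("cv must be non-negative")
  if (replicates < 1) stop("need at least one replicate")
  structure(list(cv = cv, replicates = as.integer(replicates), seed = seed),
            class = "noise_model")
}

# evaluate code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate synthetic control/trial measurement series
#'
#' Emulates the triplicate bench experiment: control rows carry the
#' dissolved concentration of a CWM-free solution (the system total over
#' its volume, constant across the ramp); trial rows carry the per-step
#' equilibrium concentrations of a ramp simulation. Absorbance readings are
#' produced by inverting the assay calibration, so the quantification chain
#' recovers the truth exactly at zero noise.
#'
#' @param truth a `"ramp_result"` from [simulate_ramp()].
#' @param cal an [assay_calibration()].
#' @param noise a [noise_model()].
#' @param a_background background absorbance folded into every final read.
#' @param noise_on `"concentration"` (default) or `"absorbance"`.
#' @return Tibble in the `measurements.csv` schema: `ethanol_pct`,
#'   `temperature_C`, `step`, `replicate`, `role`, `a_background`,
#'   `a_final`, plus the generating `conc_true`.
#' @export
generate_measurements <- function(truth, cal, noise = noise_model(),
                                  a_background = 0,
                                  noise_on = c("concentration", "absorbance")) {
  stopifnot(inherits(truth, "ramp_result"), inherits(cal, "assay_calibration"),
            inherits(noise, "noise_model"))
  noise_on <- match.arg(noise_on)
  system <- attr(truth, "system")
  control_conc <- system$total_pa_mg / system$liquid_volume_L
  grid <- expand.grid(replicate = seq_len(noise$replicates),
                      step = truth$step,
                      role = c("control", "trial"),
                      stringsAsFactors = FALSE)
  grid$temperature_C <- truth$temperature_C[grid$step]
  grid$ethanol_pct <- truth$ethanol_pct[grid$step]
  grid$conc_true <- ifelse(grid$role == "control", control_conc,
                           truth$c_pa_mg_per_L[grid$step])
  with_local_seed(noise$seed, {
    z <- stats::rnorm(nrow(grid))
    if (noise_on == "concentration") {
      conc_noisy <- grid$conc_true * (1 + noise$cv * z)
      conc_noisy <- pmax(conc_noisy, 0)
      a_final <- absorbance_from_concentration(conc_noisy, cal, a_background)
    } else {
      a_true <- absorbance_from_concentration(grid$conc_true, cal, a_background)
      a_final <- a_true * (1 + noise$cv * z)
    }
    tibble::tibble(
      ethanol_pct = grid$ethanol_pct,
      temperature_C = grid$temperature_C,
      step = grid$step,
      replicate = grid$replicate,
      role = grid$role,
      a_background = a_background,
      a_final = a_final,
      conc_true = grid$conc_true)
  })
}

#' Quantify a measurement series
#'
#' Runs the assay chain over a measurement table: converts absorbances to
#' concentrations, averages the control replicates per step, infers the
#' adsorbed amount per mg CWM for each trial replicate, and expresses each
#' replicate's desorption relative to its own step-1 adsorption.
#'
#' @param measurements table in the `measurements.csv` schema (columns
#'   `step`, `temperature_C`, `ethanol_pct`, `replicate`, `role`,
#'   `a_background`, `a_final`; a `conc_mg_per_L` column, if present, is
#'   used directly instead of the absorbances).
#' @param cal an [assay_calibration()].
#' @param volume_L,cwm_mass_mg trial geometry (defaults: the 4.5 mL / 10 mg
#'   bench scale).
#' @return Tibble with one row per trial replicate and step: `q_mg_per_mg`
#'   and `percent_desorption`.
#' @export
quantify_measurements <- function(measurements, cal,
                                  volume_L = 0.0045, cwm_mass_mg = 10) {
  m <- as.data.frame(measurements)
  if ("conc_mg_per_L" %in% names(m) && !all(is.na(m$conc_mg_per_L))) {
    m$conc <- m$conc_mg_per_L
  } else {
    m$conc <- concentration_from_absorbance(m$a_final, cal, m$a_background)
  }
  ctrl <- m[m$role == "control", ] |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(control_mean = mean(.data$conc), .groups = "drop")
  tr <- dplyr::inner_join(m[m$role == "trial", ], ctrl, by = "step")
  tr$q_mg_per_mg <- adsorbed_per_mg(tr$control_mean, tr$conc,
                                    volume_L, cwm_mass_mg)
  tr <- tr |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$step, .by_group = TRUE) |>
    dplyr::mutate(percent_desorption =
                    100 * (.data$q_mg_per_mg[1] - .data$q_mg_per_mg) /
                    .data$q_mg_per_mg[1]) |>
    dplyr::ungroup()
  tibble::as_tibble(tr[, c("ethanol_pct", "temperature_C", "step", "replicate",
                           "conc", "control_mean", "q_mg_per_mg",
                           "percent_desorption")]) |>
    dplyr::rename(conc_mg_per_L = "conc")
}

#' Generate noisy isotherm points
#'
#' @param params a [langmuir_parameters()] object (the generating truth).
#' @param c_grid equilibrium concentrations, mg/L.
#' @param noise a [noise_model()]; each grid concentration is measured
#'   `noise$replicates` times with multiplicative noise on q.
#' @return Tibble in the `isotherm_points.csv` schema
#'   (`c_mg_per_L`, `q_mg_per_mg`).
#' @export
generate_isotherm_points <- function(params, c_grid, noise = noise_model(cv = 0, replicates = 1)) {
  stopifnot(inherits(params, "langmuir_parameters"),
            inherits(noise, "noise_model"))
  if (length(c_grid) == 0L) stop("empty concentration grid")
  cc <- rep(c_grid, each = noise$replicates)
  q <- isotherm_q(cc, params)
  with_local_seed(noise$seed, {
    qn <- q * (1 + noise$cv * stats::rnorm(length(q)))
    tibble::tibble(c_mg_per_L = cc, q_mg_per_mg = pmax(qn, 0))
  })
}

#' Construct a subunit profile with target composition
#'
#' Deterministically builds a phloroglucinolysis profile whose computed mean
#' degree of polymerization, percent gallo units and percent galloylation
#' match the targets: the terminal pool is `total/mdp`, gallate and
#' trihydroxylated subunits are placed in the extension pool first
#' (overflowing to the terminal pool for short polymers), and the remainder
#' is filled with (epi)catechin.
#'
#' @param target_mdp target mean degree of polymerization, >= 1.
#' @param pct_gallo target percent epigallocatechin units.
#' @param pct_galloylation target percent epicatechin gallate units.
#' @param total_nmol total subunit amount, nmol.
#' @param seed unused placeholder for generator API symmetry.
#' @return A [subunit_profile()].
#' @examples
#' p <- generate_subunit_profile(8, pct_gallo = 10, pct_galloylation = 20)
#' c(mdp(p), percent_gallo(p), percent_galloylation(p))
#' @export
generate_subunit_profile <- function(target_mdp, pct_gallo = 0,
                                     pct_galloylation = 0,
                                     total_nmol = 1000, seed = NULL) {
  if (target_mdp < 1) stop("target_mdp must be >= 1")
  if (pct_gallo < 0 || pct_galloylation < 0 ||
      pct_gallo + pct_galloylation > 100) {
    stop("infeasible composition targets: percentages must be non-negative and sum to at most 100")
  }
  terminal_total <- total_nmol / target_mdp
  extension_total <- total_nmol - terminal_total
  egc <- pct_gallo / 100 * total_nmol
  ecg <- pct_galloylation / 100 * total_nmol

  ext <- c(`epicatechin-gallate` = 0, epigallocatechin = 0, epicatechin = 0)
  ter <- c(`epicatechin-gallate` = 0, epigallocatechin = 0,
           catechin = 0, epicatechin = 0)
  room <- extension_total
  ext["epicatechin-gallate"] <- min(ecg, room); room <- room - ext["epicatechin-gallate"]
  ter["epicatechin-gallate"] <- ecg - ext["epicatechin-gallate"]
  ext["epigallocatechin"] <- min(egc, room); room <- room - ext["epigallocatechin"]
  ter["epigallocatechin"] <- egc - ext["epigallocatechin"]
  ext["epicatechin"] <- room
  ter_room <- terminal_total - ter["epicatechin-gallate"] - ter["epigallocatechin"]
  if (ter_room < -1e-9) {
    stop("infeasible composition targets: gallate/gallo pool exceeds the profile")
  }
  ter["catechin"] <- ter_room / 2
  ter["epicatechin"] <- ter_room / 2

  d <- rbind(
    data.frame(species = names(ext), position = "extension", nmol = unname(ext)),
    data.frame(species = names(ter), position = "terminal", nmol = unname(ter)))
  subunit_profile(d[d$nmol > 0 | d$position == "terminal" & d$species == "catechin", ])
}

#' Generate a synthetic GPC trace from a lognormal mixture
#'
#' Builds the mass distribution of a polymer population as a mixture of
#' Gaussian components in log10 molar mass, and maps it through the size
#' calibration to an elution-domain trace.
#'
#' @param components data frame with columns `mean_log10_mw`, `sd_log10`,
#'   `mass_fraction` (fractions must sum to 1).
#' @param calibration data frame with columns `elution_mL`, `log10_mw`
#'   (monotone decreasing); defaults to a linear calibration spanning
#'   log10 MW 5 down to 2 over 10-30 mL.
#' @param n_points number of grid points in the trace.
#' @param seed unused placeholder for generator API symmetry.
#' @return A [gpc_trace()].
#' @export
generate_gpc_trace <- function(components, calibration = NULL,
                               n_points = 200, seed = NULL) {
  components <- as.data.frame(components)
  needed <- c("mean_log10_mw", "sd_log10", "mass_fraction")
  if (!all(needed %in% names(components))) {
    stop("components must have columns ", paste(needed, collapse = ", "))
  }
  if (!isTRUE(all.equal(sum(components$mass_fraction), 1, tolerance = 1e-8))) {
    stop("component mass fractions must sum to 1")
  }
  if (any(components$sd_log10 <= 0)) stop("sd_log10 must be positive")
  if (is.null(calibration)) {
    calibration <- data.frame(elution_mL = c(10, 30), log10_mw = c(5, 2))
  }
  elution <- seq(min(calibration$elution_mL), max(calibration$elution_mL),
                 length.out = n_points)
  log10_mw <- stats::approx(calibration$elution_mL, calibration$log10_mw,
                            xout = elution)$y
  signal <- rowSums(mapply(
    function(mu, sd, f) f * stats::dnorm(log10_mw, mu, sd),
    components$mean_log10_mw, components$sd_log10, components$mass_fraction))
  gpc_trace(elution, signal, calibration)
}
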