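#' Langmuir adsorption isotherm
#'
#' Single-layer adsorption: \eqn{q = K C S / (1 + K C)} where `q` is the mass
#' of proanthocyanidin adsorbed per mass of cell wall material at equilibrium
#' (mg PA C.U./mg CWM) and `C` the equilibrium solution concentration
#' (mg PA C.U./L). `q` is bounded by the saturation capacity `S` and strictly
#' increasing in `C`.
#'
#' @param c_pa equilibrium concentration(s), mg PA (C.U.)/L; must be >= 0.
#' @param params a [langmuir_parameters()] object.
#' @return Adsorbed amount(s), mg PA/mg CWM, same length as `c_pa`.
#' @examples
#' isotherm_q(1, langmuir_constants(1, 0.4))  # half saturation
#' @export
isotherm_q <- function(c_pa, params) {
  stopifnot(inherits(params, "langmuir_parameters"))
  if (any(!is.finite(c_pa)) || any(c_pa < 0)) {
    stop("c_pa must be finite and non-negative")
  }
  params$keq * c_pa * params$scwm / (1 + params$keq * c_pa)
}

#' Closed liquid-solid batch system
#'
#' Describes a sealed vessel with a known solution volume, mass of cell wall
#' material (the adsorbent), and total proanthocyanidin mass partitioned
#' between solution and adsorbent.
#'
#' @param liquid_volume_L solution volume, L.
#' @param cwm_mass_mg adsorbent (CWM) mass, mg.
#' @param total_pa_mg total PA in the system, mg catechin units.
#' @return Object of class `"batch_system"`.
#' @examples
#' # the bench-scale desorption experiment: 4.5 mL at 1500 mg/L on 10 mg CWM
#' batch_system(0.0045, 10, 6.75)
#' @export
batch_system <- function(liquid_volume_L, cwm_mass_mg, total_pa_mg) {
  vals <- c(liquid_volume_L, cwm_mass_mg, total_pa_mg)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all batch_system fields must be finite and non-negative")
  }
  structure(list(liquid_volume_L = liquid_volume_L,
                 cwm_mass_mg = cwm_mass_mg,
                 total_pa_mg = total_pa_mg),
            class = "batch_system")
}

#' Solve the batch adsorption equilibrium
#'
#' Substituting the Langmuir isotherm into the closed-system mass balance
#' \eqn{C V + q m = \mathrm{total}} yields a quadratic in the equilibrium
#' concentration `C`:
#' \deqn{V K C^2 + (V + m K S - K\,\mathrm{total})\, C - \mathrm{total} = 0.}
#' The product of its roots is \eqn{-\mathrm{total}/(V K) \le 0}, so exactly
#' one root is non-negative; that root is returned and checked to lie in
#' `[0, total/V]`. With no adsorbent the solution is trivially
#' `C = total/V`, `q = 0`.
#'
#' @param system a [batch_system()].
#' @param params a [langmuir_parameters()] object.
#' @return Object of class `"equilibrium_state"` with `c_pa_mg_per_L`,
#'   `q_pa_mg_per_mg`, `adsorbed_mg` and `mass_residual` (absolute mass
#'   balance defect, mg).
#' @examples
#' sys <- batch_system(1, 1000, 201)
#' solve_batch_equilibrium(sys, langmuir_constants(1, 0.4))
#' @export
solve_batch_equilibrium <- function(system, params) {
  stopifnot(inherits(system, "batch_system"),
            inherits(params, "langmuir_parameters"))
  V <- system$liquid_volume_L
  m <- system$cwm_mass_mg
  total <- system$total_pa_mg
  K <- params$keq
  S <- params$scwm

  if (V == 0) {
    if (total > 0) {
      stop("degenerate system: zero liquid volume with nonzero total PA")
    }
    return(new_equilibrium_state(0, 0, m, total))
  }
  if (m == 0 || total == 0) {
    return(new_equilibrium_state(total / V, 0, m, total))
  }

  a <- V * K
  b <- V + m * K * S - K * total
  disc <- b^2 + 4 * a * total
  if (disc < 0) {
    stop("internal consistency failure: negative discriminant in batch solve")
  }
  # numerically stable quadratic roots (avoid cancellation when b > 0)
  s <- sqrt(disc)
  if (b >= 0) {
    c_pos <- 2 * total / (b + s)
    c_other <- -(b + s) / (2 * a)
  } else {
    c_pos <- (-b + s) / (2 * a)
    c_other <- 2 * total / (b - s)
  }
  if (c_pos < 0 || c_pos > total / V * (1 + 1e-12)) {
    stop("internal consistency failure: admissible root outside [0, total/V]")
  }
  if (c_other > 0 && c_other <= total / V) {
    stop("internal consistency failure: both quadratic roots admissible")
  }
  q <- isotherm_q(c_pos, params)
  new_equilibrium_state(c_pos, q, m, total, V)
}

new_equilibrium_state <- function(c_pa, q_pa, m, total, V = NULL) {
  adsorbed <- q_pa * m
  residual <- if (is.null(V)) 0 else abs(c_pa * V + adsorbed - total)
  structure(list(c_pa_mg_per_L = c_pa,
                 q_pa_mg_per_mg = q_pa,
                 adsorbed_mg = adsorbed,
                 mass_residual = residual),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "Equilibrium: C = %.4g mg/L, q = %.4g mg/mg, adsorbed = %.4g mg (residual %.2e)\n",
    x$c_pa_mg_per_L, x$q_pa_mg_per_mg, x$adsorbed_mg, x$mass_residual))
  invisible(x)
}

#' Fit Langmuir parameters to isotherm points
#'
#' Nonlinear least squares on \eqn{q = K C S/(1 + K C)}, with positivity
#' bounds on both parameters. Starting values follow standard isotherm
#' fitting practice: `S0 = 1.1 * max(q)` and `K0 = 1/median(c)` over the
#' nonzero concentrations.
#'
#' @param points data frame with columns `c_mg_per_L` and `q_mg_per_mg`
#'   (the on-disk schema of `isotherm_points.csv`), or columns `c` and `q`.
#' @param start optional named list overriding the starting values, with
#'   elements `keq` and `scwm`.
#' @return Object of class `"langmuir_fit"`: `keq`, `scwm`, `converged`,
#'   `residual_norm` (sum of squared residuals), `degenerate` flag and the
#'   underlying `nls` fit.
#' @examples
#' pts <- generate_isotherm_points(langmuir_constants(0.01, 0.3),
#'                                 c_grid = seq(50, 1500, length.out = 6))
#' fit_langmuir(pts)
#' @export
fit_langmuir <- function(points, start = NULL) {
  points <- as.data.frame(points)
  if (all(c("c_mg_per_L", "q_mg_per_mg") %in% names(points))) {
    cc <- points$c_mg_per_L
    qq <- points$q_mg_per_mg
  } else if (all(c("c", "q") %in% names(points))) {
    cc <- points$c
    qq <- points$q
  } else {
    stop("points must have columns c_mg_per_L/q_mg_per_mg (or c/q)")
  }
  if (length(cc) < 3L) stop("need at least 3 isotherm points")
  if (any(cc < 0) || any(qq < 0)) stop("isotherm points must be non-negative")
  if (length(unique(cc)) < 2L) {
    stop("degenerate isotherm points: need at least two distinct concentrations")
  }
  if (all(qq == 0)) {
    return(structure(list(keq = NA_real_, scwm = 0, converged = FALSE,
                          residual_norm = 0, degenerate = TRUE, fit = NULL),
                     class = "langmuir_fit"))
  }
  if (is.null(start)) {
    start <- list(keq = 1 / stats::median(cc[cc > 0]),
                  scwm = 1.1 * max(qq))
  }
  dat <- data.frame(cc = cc, qq = qq)
  fit <- tryCatch(
    minpack.lm::nlsLM(qq ~ keq * cc * scwm / (1 + keq * cc),
                      data = dat, start = start,
                      lower = c(keq = 1e-12, scwm = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("Langmuir fit failed to converge: ", conditionMessage(fit))
  }
  est <- stats::coef(fit)
  structure(list(keq = unname(est["keq"]), scwm = unname(est["scwm"]),
                 converged = fit$convInfo$isConv,
                 residual_norm = sum(stats::residuals(fit)^2),
                 degenerate = FALSE, fit = fit),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Langmuir fit: degenerate (all q = 0); SCWM at zero boundary\n")
  } else {
    cat(sprintf(
      "Langmuir fit: Keq = %.4g, SCWM = %.4g (converged: %s, SSR = %.3e)\n",
      x$keq, x$scwm, x$converged, x$residual_norm))
  }
  invisible(x)
}
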