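#' @importFrom rlang .data
NULL

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  d
}

#' Read and write the package's CSV schemas
#'
#' All files are headered, UTF-8, period-decimal CSV; temperatures in
#' degrees Celsius, concentrations in mg catechin units per litre. Every
#' writer's output is readable by its paired reader.
#'
#' @param path file path.
#' @param x table to write.
#' @name schemas
NULL

#' @rdname schemas
#' @export
read_isotherm_points <- function(path) {
  read_checked(path, c("c_mg_per_L", "q_mg_per_mg"))
}

#' @rdname schemas
#' @export
write_isotherm_points <- function(x, path) {
  readr::write_csv(x[, c("c_mg_per_L", "q_mg_per_mg")], path)
  invisible(path)
}

#' @rdname schemas
#' @export
read_measurements <- function(path) {
  d <- read_checked(path, c("ethanol_pct", "temperature_C", "step",
                            "replicate", "role"))
  if (!("conc_mg_per_L" %in% names(d)) &&
      !all(c("a_background", "a_final") %in% names(d))) {
    stop("measurements need either conc_mg_per_L or a_background/a_final columns")
  }
  d
}

#' @rdname schemas
#' @export
write_measurements <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname schemas
#' @export
read_calibration_standards <- function(path) {
  read_checked(path, c("conc_mg_per_L", "absorbance"))
}

#' @rdname schemas
#' @export
read_subunits <- function(path) {
  read_checked(path, c("species", "position", "nmol"))
}

#' @rdname schemas
#' @export
write_subunits <- function(x, path) {
  d <- if (inherits(x, "subunit_profile")) x$data else x
  readr::write_csv(d[, c("species", "position", "nmol")], path)
  invisible(path)
}

#' @rdname schemas
#' @param cal_path path of the GPC calibration file (`elution_mL`,
#'   `log10_mw`).
#' @export
read_gpc_trace <- function(path, cal_path) {
  d <- read_checked(path, c("elution_mL", "signal"))
  cal <- read_checked(cal_path, c("elution_mL", "log10_mw"))
  gpc_trace(d$elution_mL, d$signal, cal)
}

#' @rdname schemas
#' @export
write_gpc_trace <- function(x, path, cal_path = NULL) {
  stopifnot(inherits(x, "gpc_trace"))
  readr::write_csv(tibble::tibble(elution_mL = x$elution_mL, signal = x$signal),
                   path)
  if (!is.null(cal_path)) readr::write_csv(x$calibration, cal_path)
  invisible(path)
}

#' Default run configuration
#'
#' The defaults encode the bench study conditions: the 15 to 35 degC ramp,
#' the 4.5 mL / 10 mg CWM / 1500 mg/L trial geometry, triplicate
#' measurements with 3 % CV multiplicative noise, and the 750-berry
#' winemaking scenario.
#'
#' @return Nested named list (the `RunConfig` structure).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    model = list(coefficients = list(set = "default", keq = NULL, scwm = NULL)),
    ramp = list(ethanol_pct = 15, temperatures_C = c(15, 22.5, 30, 35),
                mode = "equilibrium", fractions = NULL, phi = 0,
                withdrawal_uL = 0),
    system = list(volume_L = 0.0045, cwm_mass_mg = 10, pa_mg_per_L = 1500),
    assay = list(slope = 0.001, intercept = 0,
                 dilution_factor = 1000 / 75, background_scale = 0.875),
    noise = list(cv = 0.03, replicates = 3L, on = "concentration"),
    scenario = list(berries_per_L = 750, cwm_mg_per_berry = 10,
                    pa_mg_per_L = 1500, volume_L = 1,
                    coldsoak_temperature_C = 15, coldsoak_ethanol_pct = 0,
                    final_temperature_C = 35, final_ethanol_pct = 15,
                    final_desorption_fraction = 0.4796),
    composition = list(target_mdp = 8, pct_gallo = 20, pct_galloylation = 10,
                       total_nmol = 1000,
                       gpc_components = list(
                         list(mean_log10_mw = 3.3, sd_log10 = 0.25,
                              mass_fraction = 0.6),
                         list(mean_log10_mw = 2.6, sd_log10 = 0.2,
                              mass_fraction = 0.4))),
    files = list(measurements = NULL, calibration = NULL,
                 isotherm_points = NULL, subunits = NULL,
                 gpc = NULL, gpc_cal = NULL)
  )
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- if (prefix == "") key else paste0(prefix, ".", key)
    if (!(key %in% names(defaults))) {
      stop("unknown config key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, applies the [default_config()] defaults, rejects
#' unknown keys with a named error, and checks that every referenced file
#' exists.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user)
  }
  if (!cfg$model$coefficients$set %in% c("default", "printed")) {
    stop("model.coefficients.set must be 'default' or 'printed'")
  }
  if (!cfg$ramp$mode %in% c("equilibrium", "empirical", "partial")) {
    stop("ramp.mode must be equilibrium, empirical or partial")
  }
  for (nm in names(cfg$files)) {
    f <- cfg$files[[nm]]
    if (!is.null(f) && !file.exists(f)) {
      stop("config references missing file (files.", nm, "): ", f)
    }
  }
  cfg
}

surface_override <- function(spec, fallback) {
  if (is.null(spec)) return(fallback)
  rational_surface(numerator = unlist(spec$numerator),
                   denominator = unlist(spec$denominator),
                   label = fallback$label)
}

#' Parameter surfaces implied by a configuration
#'
#' @param config a config list from [load_config()].
#' @return List with `keq` and `scwm` surfaces, honouring any coefficient
#'   overrides in `model.coefficients`.
#' @export
config_surfaces <- function(config) {
  base <- surface_coefficients(config$model$coefficients$set)
  list(keq = surface_override(config$model$coefficients$keq, base$keq),
       scwm = surface_override(config$model$coefficients$scwm, base$scwm))
}

config_calibration <- function(config) {
  assay_calibration(slope = config$assay$slope,
                    intercept = config$assay$intercept,
                    dilution_factor = config$assay$dilution_factor,
                    background_scale = config$assay$background_scale)
}

config_ramp_truth <- function(config) {
  sys <- batch_system(config$system$volume_L, config$system$cwm_mass_mg,
                      config$system$pa_mg_per_L * config$system$volume_L)
  sched <- ramp_schedule(config$ramp$ethanol_pct, config$ramp$temperatures_C)
  simulate_ramp(sys, sched, config_surfaces(config),
                mode = config$ramp$mode,
                fractions = config$ramp$fractions,
                phi = config$ramp$phi,
                withdrawal_uL = config$ramp$withdrawal_uL)
}

pipeline_log <- function(out_dir, command, lines) {
  path <- file.path(out_dir, "pasorption.log")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     command, lines), con)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Ties the package stages into file-to-file commands. Each command writes
#' its output CSVs (and a log line) under `out_dir` and is deterministic
#' given the config seed.
#'
#' * `"synth"` - ramp truth + noisy triplicate measurements
#'   (`measurements.csv`, `truth.json`).
#' * `"quantify"` - assay chain over measurements (`quantified.csv`).
#' * `"stats"` - desorption summary with significance letters
#'   (`stats.csv`).
#' * `"simulate-ramp"` - ramp simulation table (`ramp.csv`).
#' * `"compare-model"` - model-vs-data error report (`model_error.csv`).
#' * `"scenario"` - winemaking extrapolation (`scenario.csv`).
#' * `"composition"` - compositional metrics (`composition.csv`).
#'
#' @param config config list from [load_config()].
#' @param command one of the stage names above.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_pipeline <- function(config, command, out_dir = ".") {
  command <- match.arg(command, c("synth", "quantify", "stats",
                                  "simulate-ramp", "compare-model",
                                  "scenario", "composition"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  cal <- config_calibration(config)

  if (command == "synth") {
    truth <- config_ramp_truth(config)
    noise <- noise_model(config$noise$cv, config$noise$replicates,
                         seed = config$seed)
    meas <- generate_measurements(truth, cal, noise,
                                  noise_on = config$noise$on)
    p1 <- file.path(out_dir, "measurements.csv")
    write_measurements(meas, p1)
    p2 <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(percent_desorption = truth$percent_desorption,
           adsorbed_mg = truth$adsorbed_mg,
           c_pa_mg_per_L = truth$c_pa_mg_per_L,
           temperature_C = truth$temperature_C,
           ethanol_pct = config$ramp$ethanol_pct,
           seed = config$seed),
      p2, digits = NA, auto_unbox = TRUE)
    paths <- c(measurements = p1, truth = p2)
  } else if (command == "quantify") {
    src <- config$files$measurements %||% file.path(out_dir, "measurements.csv")
    meas <- read_measurements(src)
    quant <- quantify_measurements(meas, cal,
                                   volume_L = config$system$volume_L,
                                   cwm_mass_mg = config$system$cwm_mass_mg)
    p <- file.path(out_dir, "quantified.csv")
    readr::write_csv(quant, p)
    paths <- c(quantified = p)
  } else if (command == "stats") {
    src <- file.path(out_dir, "quantified.csv")
    quant <- read_checked(src, c("ethanol_pct", "temperature_C", "step",
                                 "replicate", "percent_desorption"))
    quant <- quant[quant$step > 1, ]
    summ <- summarize_desorption(quant)
    letters_within <- anova_letters(quant$percent_desorption,
                                    quant$temperature_C)
    summ$letter_within_ethanol <-
      letters_within$letter[match(summ$temperature_C, letters_within$group)]
    summ$letter_within_temperature <- NA_character_
    p <- file.path(out_dir, "stats.csv")
    readr::write_csv(summ, p)
    paths <- c(stats = p)
  } else if (command == "simulate-ramp") {
    truth <- config_ramp_truth(config)
    p <- file.path(out_dir, "ramp.csv")
    readr::write_csv(tibble::as_tibble(truth), p)
    paths <- c(ramp = p)
  } else if (command == "compare-model") {
    src <- config$files$isotherm_points
    if (is.null(src)) stop("compare-model needs files.isotherm_points")
    pts <- read_checked(src, c("c_mg_per_L", "q_mg_per_mg",
                               "temperature_C", "ethanol_pct"))
    rep <- model_error(pts, config_surfaces(config))
    p <- file.path(out_dir, "model_error.csv")
    readr::write_csv(rep, p)
    paths <- c(model_error = p)
  } else if (command == "scenario") {
    spec <- do.call(scenario_spec, config$scenario)
    rep <- scenario_report(spec, config_surfaces(config))
    out <- tibble::as_tibble(rep)
    out$difference_mg <- attr(rep, "difference_mg")
    out$difference_mg_per_L <- attr(rep, "difference_mg_per_L")
    p <- file.path(out_dir, "scenario.csv")
    readr::write_csv(out, p)
    paths <- c(scenario = p)
  } else if (command == "composition") {
    if (!is.null(config$files$subunits)) {
      prof <- subunit_profile(read_subunits(config$files$subunits))
    } else {
      prof <- generate_subunit_profile(config$composition$target_mdp,
                                       config$composition$pct_gallo,
                                       config$composition$pct_galloylation,
                                       config$composition$total_nmol)
    }
    if (!is.null(config$files$gpc)) {
      trace <- read_gpc_trace(config$files$gpc, config$files$gpc_cal)
    } else {
      comps <- do.call(rbind, lapply(config$composition$gpc_components,
                                     as.data.frame))
      trace <- generate_gpc_trace(comps)
    }
    out <- tibble::tibble(
      mdp = mdp(prof),
      pct_galloylation = percent_galloylation(prof),
      pct_gallo = percent_gallo(prof),
      average_mw = average_mw(prof),
      mw_at_90pct_cumulative_mass = molar_mass_at_quantile(trace, 0.9))
    p <- file.path(out_dir, "composition.csv")
    readr::write_csv(out, p)
    paths <- c(composition = p)
  }
  pipeline_log(out_dir, command, paste("wrote", paths))
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
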