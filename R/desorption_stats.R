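#' Summarize per-replicate desorption percentages
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' percent desorption per (ethanol, temperature) cell, mirroring how the
#' triplicate bench measurements are reported.
#'
#' @param data data frame with columns `ethanol_pct`, `temperature_C` and
#'   `percent_desorption` (one row per replicate).
#' @return Tibble with `ethanol_pct`, `temperature_C`, `mean_pct`, `sd_pct`
#'   (`NA` for single-replicate cells) and `n`.
#' @examples
#' d <- data.frame(ethanol_pct = 15, temperature_C = 22.5,
#'                 percent_desorption = c(26.36, 26.73, 27.10))
#' summarize_desorption(d)
#' @export
summarize_desorption <- function(data) {
  data <- as.data.frame(data)
  needed <- c("ethanol_pct", "temperature_C", "percent_desorption")
  if (!all(needed %in% names(data))) {
    stop("data must have columns ", paste(needed, collapse = ", "))
  }
  if (nrow(data) == 0L) stop("no replicates supplied")
  if (any(is.na(data$percent_desorption))) {
    bad <- data[is.na(data$percent_desorption), ][1, ]
    stop(sprintf("empty cell at ethanol %.1f %%, %.1f degC",
                 bad$ethanol_pct, bad$temperature_C))
  }
  data |>
    dplyr::group_by(.data$ethanol_pct, .data$temperature_C) |>
    dplyr::summarise(
      mean_pct = mean(.data$percent_desorption),
      sd_pct = if (dplyr::n() > 1L) stats::sd(.data$percent_desorption) else NA_real_,
      n = dplyr::n(),
      .groups = "drop") |>
    tibble::as_tibble()
}

#' Compact letter display from one-way ANOVA with Tukey HSD
#'
#' One-way analysis of variance across groups at level `alpha`; when the
#' overall F test is significant, all-pairs Tukey HSD comparisons feed a
#' compact letter display in which groups sharing a letter are not
#' significantly different. When every group has zero within-group variance
#' the F statistic is undefined and letters are assigned by exact equality
#' of the group values instead.
#'
#' The bench study reports plain spreadsheet ANOVA with an unstated
#' letter-assignment procedure; Tukey HSD is the standard generator of
#' letter displays and is used here as a deliberate, documented choice.
#'
#' @param values numeric response values.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level (default 0.05).
#' @return Tibble with `group`, `n`, `mean` and `letter`, ordered by
#'   decreasing mean ("a" = highest).
#' @examples
#' anova_letters(c(1, 1.1, 0.9, 5, 5.2, 4.9), rep(c("lo", "hi"), each = 3))
#' @export
anova_letters <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  counts <- table(g)
  if (any(counts < 2L)) stop("need at least two replicates per group")
  means <- tapply(values, g, mean)
  wvar <- tapply(values, g, stats::var)

  if (all(wvar == 0)) {
    # degenerate: no residual variance, group by exact equality
    distinct <- sort(unique(means), decreasing = TRUE)
    letter <- stats::setNames(letters[match(means, distinct)], names(means))
  } else {
    df <- data.frame(y = values, g = g)
    fit <- stats::aov(y ~ g, data = df)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(p) || p >= alpha) {
      letter <- stats::setNames(rep("a", nlevels(g)), levels(g))
    } else {
      glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
      cld <- multcomp::cld(glht_fit, level = alpha, decreasing = TRUE)
      letter <- cld$mcletters$Letters
    }
  }
  ord <- order(-means)
  tibble::tibble(group = names(means)[ord],
                 n = as.integer(counts[names(means)][ord]),
                 mean = as.numeric(means[ord]),
                 letter = unname(letter[names(means)][ord]))
}

#' Model-versus-data error report
#'
#' For each observed isotherm point the Langmuir prediction at that point's
#' condition is computed and compared to the observation. Reported per
#' (ethanol, temperature) cell:
#'
#' * `mae` - mean absolute error in q, mg/mg;
#' * `mpe` - mean percent error, with the observed q as denominator; points
#'   with `q_obs = 0` are excluded from the percent error and counted in
#'   `n_excluded`;
#' * `bias` - signed mean of (predicted - observed), labelled
#'   `"overestimates"` / `"underestimates"` / `"unbiased"`.
#'
#' @param points data frame with columns `c_mg_per_L`, `q_mg_per_mg`
#'   (observed), `temperature_C`, `ethanol_pct`.
#' @param coefficients surfaces from [surface_coefficients()].
#' @return Tibble, one row per condition cell.
#' @export
model_error <- function(points, coefficients = surface_coefficients()) {
  points <- as.data.frame(points)
  needed <- c("c_mg_per_L", "q_mg_per_mg", "temperature_C", "ethanol_pct")
  if (!all(needed %in% names(points))) {
    stop("points must have columns ", paste(needed, collapse = ", "))
  }
  if (nrow(points) == 0L) stop("no points supplied")
  cells <- split(points, interaction(points$ethanol_pct, points$temperature_C,
                                     drop = TRUE))
  rows <- lapply(cells, function(cell) {
    params <- langmuir_parameters(
      condition(cell$temperature_C[1], cell$ethanol_pct[1]), coefficients)
    pred <- isotherm_q(cell$c_mg_per_L, params)
    err <- pred - cell$q_mg_per_mg
    nonzero <- cell$q_mg_per_mg != 0
    bias <- mean(err)
    tibble::tibble(
      ethanol_pct = cell$ethanol_pct[1],
      temperature_C = cell$temperature_C[1],
      n = nrow(cell),
      mae = mean(abs(err)),
      mpe = if (any(nonzero)) {
        mean(abs(err[nonzero]) / cell$q_mg_per_mg[nonzero]) * 100
      } else NA_real_,
      n_excluded = sum(!nonzero),
      bias = bias,
      direction = if (bias > 0) "overestimates"
                  else if (bias < 0) "underestimates" else "unbiased")
  })
  out <- do.call(rbind, rows)
  out[order(out$ethanol_pct, out$temperature_C), ]
}

#' Benchmark desorption percentages from the bench ramp study
#'
#' Mean percent desorption of initially adsorbed PA (and sample SD, n = 3)
#' measured on grape skin CWM as the incubation temperature was raised from
#' 15 degC, at four ethanol levels. These measured values drive the
#' `"empirical"` ramp mode and the cold-soak arm of the winemaking scenario.
#'
#' @return Tibble with `ethanol_pct`, `temperature_C`, `mean_pct`, `sd_pct`.
#' @examples
#' reference_desorption()
#' @export
reference_desorption <- function() {
  tibble::tibble(
    ethanol_pct = rep(c(0, 7.5, 12, 15), each = 3),
    temperature_C = rep(c(22.5, 30, 35), times = 4),
    mean_pct = c(2.82, 7.49, 13.35,
                 8.60, 22.30, 27.88,
                 17.48, 25.24, 31.59,
                 26.73, 37.36, 47.96),
    sd_pct = c(3.39, 5.51, 5.62,
               2.01, 3.58, 3.38,
               1.46, 9.94, 10.26,
               0.37, 1.71, 3.37)
  )
}

#' Measured desorption fractions at one ethanol level
#'
#' Convenience accessor over [reference_desorption()]: the mean desorption
#' percentages above 15 degC at the requested ethanol level, as fractions.
#'
#' @param ethanol_pct one of 0, 7.5, 12, 15.
#' @return Numeric vector of fractions, ordered by temperature.
#' @export
desorption_fractions <- function(ethanol_pct) {
  ref <- reference_desorption()
  rows <- ref[ref$ethanol_pct == ethanol_pct, ]
  if (nrow(rows) == 0L) {
    stop("no measured desorption fractions at ethanol ", ethanol_pct, " %")
  }
  rows$mean_pct[order(rows$temperature_C)] / 100
}
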