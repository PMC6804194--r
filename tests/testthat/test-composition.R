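make_profile <- function(...) subunit_profile(data.frame(...))

test_that("mdp is the total-to-terminal mole ratio", {
  p <- make_profile(species = c("catechin", "epicatechin"),
                    position = c("terminal", "extension"),
                    nmol = c(1, 3))
  expect_equal(mdp(p), 4)

  mono <- make_profile(species = "catechin", position = "terminal", nmol = 5)
  expect_equal(mdp(mono), 1)

  mixed <- make_profile(
    species = c("catechin", "epicatechin", "epicatechin", "epigallocatechin"),
    position = c("terminal", "terminal", "extension", "extension"),
    nmol = c(0.5, 0.5, 8, 1))
  expect_equal(mdp(mixed), 10)

  no_term <- make_profile(species = "epicatechin", position = "extension",
                          nmol = 1)
  expect_error(mdp(no_term), "terminal")
})

test_that("percent metrics are molar shares of the full pool", {
  p <- make_profile(
    species = c("catechin", "epicatechin-gallate", "epigallocatechin"),
    position = c("terminal", "extension", "extension"),
    nmol = c(7, 2, 1))
  expect_equal(percent_galloylation(p), 20)
  expect_equal(percent_gallo(p), 10)

  plain <- make_profile(species = "catechin", position = "terminal", nmol = 3)
  expect_equal(percent_galloylation(plain), 0)
  expect_equal(percent_gallo(plain), 0)

  all_ecg <- make_profile(species = c("epicatechin-gallate", "epicatechin-gallate"),
                          position = c("terminal", "extension"), nmol = c(1, 4))
  expect_equal(percent_galloylation(all_ecg), 100)
})

test_that("control-trial difference in percent gallo is plain subtraction", {
  ctrl <- make_profile(
    species = c("catechin", "epigallocatechin"),
    position = c("terminal", "extension"), nmol = c(80, 20))
  trial <- make_profile(
    species = c("catechin", "epigallocatechin"),
    position = c("terminal", "extension"), nmol = c(77, 23))
  expect_equal(percent_gallo(trial) - percent_gallo(ctrl), 3)
})

test_that("average_mw follows the definition and the brute-force identity", {
  mono <- make_profile(species = "catechin", position = "terminal", nmol = 2)
  expect_equal(average_mw(mono), 290.27)

  ec4 <- make_profile(species = c("epicatechin", "epicatechin"),
                      position = c("terminal", "extension"), nmol = c(1, 3))
  expect_equal(average_mw(ec4), 4 * 290.27)

  # brute force on random profiles: sum(n_i * MW_i) / n_terminal
  set.seed(21)
  mw <- subunit_mw_table()
  for (i in 1:20) {
    d <- data.frame(
      species = sample(names(mw), 6, replace = TRUE),
      position = c("terminal", sample(c("terminal", "extension"), 5,
                                      replace = TRUE)),
      nmol = runif(6, 0.1, 10))
    p <- subunit_profile(d)
    brute <- sum(d$nmol * mw[d$species]) / sum(d$nmol[d$position == "terminal"])
    expect_equal(average_mw(p), brute)
  }
})

test_that("composition metrics respect their structural bounds", {
  set.seed(22)
  mw <- subunit_mw_table()
  for (i in 1:20) {
    d <- data.frame(
      species = sample(names(mw), 8, replace = TRUE),
      position = c("terminal", sample(c("terminal", "extension"), 7,
                                      replace = TRUE)),
      nmol = runif(8, 0.1, 10))
    p <- subunit_profile(d)
    expect_gte(mdp(p), 1)
    expect_true(percent_gallo(p) >= 0 && percent_gallo(p) <= 100)
    expect_true(percent_galloylation(p) >= 0 && percent_galloylation(p) <= 100)
    # the two marked categories are disjoint shares of the same pool
    expect_lte(percent_gallo(p) + percent_galloylation(p), 100 + 1e-9)
  }
})

test_that("molar_mass_at_quantile locates mass quantiles", {
  cal <- data.frame(elution_mL = c(10, 30), log10_mw = c(5, 2))
  # monodisperse peak: any quantile returns its molar mass
  el <- seq(10, 30, length.out = 201)
  lm10 <- approx(cal$elution_mL, cal$log10_mw, xout = el)$y
  peak_idx <- which.min(abs(lm10 - log10(2000)))
  mono_sig <- replace(numeric(length(el)), peak_idx, 1)
  mono <- gpc_trace(el, mono_sig, cal)
  peak_mw <- 10^lm10[peak_idx]
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(molar_mass_at_quantile(mono, q), peak_mw)
  }

  # equal-mass peaks at 1000 and 3000: the 90 % quantile is in the high peak
  two <- generate_gpc_trace(data.frame(
    mean_log10_mw = c(3, log10(3000)), sd_log10 = c(0.01, 0.01),
    mass_fraction = c(0.5, 0.5)), cal)
  expect_equal(molar_mass_at_quantile(two, 0.9), 3000, tolerance = 0.02)

  # brute-force oracle: direct cumulative sum over (mw, mass) pairs
  brute_quantile <- function(trace, q) {
    lm <- approx(trace$calibration$elution_mL, trace$calibration$log10_mw,
                 xout = trace$elution_mL, rule = 2)$y
    d <- data.frame(mw = 10^lm, mass = trace$signal)
    d <- d[order(d$mw), ]
    cum <- cumsum(d$mass) / sum(d$mass)
    i <- which(cum >= q)[1]
    if (i == 1) return(d$mw[1])
    d$mw[i - 1] + (q - cum[i - 1]) / (cum[i] - cum[i - 1]) *
      (d$mw[i] - d$mw[i - 1])
  }
  set.seed(31)
  for (i in 1:10) {
    comps <- data.frame(mean_log10_mw = runif(2, 2.5, 4.5),
                        sd_log10 = runif(2, 0.05, 0.3),
                        mass_fraction = c(0.5, 0.5))
    tr <- generate_gpc_trace(comps, cal)
    for (q in c(0.25, 0.5, 0.9)) {
      expect_equal(molar_mass_at_quantile(tr, q), brute_quantile(tr, q))
    }
  }
})

test_that("molar_mass_at_quantile is non-decreasing in the quantile", {
  tr <- generate_gpc_trace(data.frame(
    mean_log10_mw = c(2.8, 3.8), sd_log10 = c(0.2, 0.3),
    mass_fraction = c(0.4, 0.6)))
  qs <- seq(0.05, 0.95, by = 0.05)
  mws <- vapply(qs, function(q) molar_mass_at_quantile(tr, q), numeric(1))
  expect_true(all(diff(mws) >= 0))
})

test_that("GPC inputs are validated", {
  cal <- data.frame(elution_mL = c(10, 30), log10_mw = c(5, 2))
  expect_error(gpc_trace(c(1, 2), c(0.1, -0.2), cal), "non-negative")
  bad_cal <- data.frame(elution_mL = c(10, 30), log10_mw = c(2, 5))
  expect_error(gpc_trace(c(1, 2), c(0.1, 0.2), bad_cal), "decreasing")
  zero <- gpc_trace(c(1, 2), c(0, 0), cal)
  expect_error(molar_mass_at_quantile(zero, 0.9), "all-zero")
  expect_error(molar_mass_at_quantile(gpc_trace(c(1, 2), c(1, 1), cal), 1.2),
               "quantile")
})
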