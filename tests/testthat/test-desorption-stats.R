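test_that("summarize_desorption computes mean and n-1 standard deviation", {
  d <- data.frame(ethanol_pct = 15, temperature_C = 35,
                  percent_desorption = c(47.96, 47.96, 47.96))
  s <- summarize_desorption(d)
  expect_equal(s$mean_pct, 47.96)
  expect_equal(s$sd_pct, 0)

  d2 <- data.frame(ethanol_pct = 15, temperature_C = 22.5,
                   percent_desorption = c(26.36, 26.73, 27.10))
  s2 <- summarize_desorption(d2)
  expect_equal(s2$mean_pct, 26.73)
  expect_equal(s2$sd_pct, 0.37)

  # a single replicate has no dispersion estimate
  s1 <- summarize_desorption(data.frame(ethanol_pct = 0, temperature_C = 30,
                                        percent_desorption = 5))
  expect_equal(s1$mean_pct, 5)
  expect_true(is.na(s1$sd_pct))
  expect_equal(s1$n, 1L)
})

test_that("summarize_desorption is permutation-invariant and names empty cells", {
  set.seed(3)
  d <- data.frame(ethanol_pct = rep(c(0, 15), each = 6),
                  temperature_C = rep(c(30, 35), times = 6),
                  percent_desorption = runif(12, 0, 50))
  s1 <- summarize_desorption(d)
  s2 <- summarize_desorption(d[sample(nrow(d)), ])
  expect_equal(s1, s2)
  bad <- data.frame(ethanol_pct = 12, temperature_C = 30,
                    percent_desorption = NA_real_)
  expect_error(summarize_desorption(bad), "12.0 %, 30.0 degC")
})

test_that("anova_letters groups identical and well-separated data correctly", {
  same <- anova_letters(rep(1.5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$letter == "a"))

  set.seed(5)
  vals <- c(0, 0, 0, 100, 100, 100, 200, 200, 200) + rnorm(9, sd = 1e-3)
  sep <- anova_letters(vals, rep(c("g0", "g100", "g200"), each = 3))
  expect_equal(length(unique(sep$letter)), 3L)
  # letters ordered by decreasing mean, highest gets "a"
  expect_equal(sep$group[1], "g200")
  expect_equal(sep$letter[1], "a")
})

test_that("anova_letters handles zero within-group variance by exact equality", {
  out <- anova_letters(c(1, 1, 1, 2, 2, 2, 2, 2, 2),
                       rep(c("x", "y", "z"), each = 3))
  expect_equal(out$letter[out$group == "y"], out$letter[out$group == "z"])
  expect_false(out$letter[out$group == "x"] == out$letter[out$group == "y"])
})

test_that("anova_letters validates its inputs", {
  expect_error(anova_letters(1:3, c("a", "a", "a")), "two groups")
  expect_error(anova_letters(1:3, c("a", "a", "b")), "two replicates")
})

test_that("model_error reports zero error for perfect predictions", {
  params <- langmuir_parameters(condition(25, 0))
  cgrid <- c(200, 600, 1200)
  pts <- data.frame(c_mg_per_L = cgrid,
                    q_mg_per_mg = isotherm_q(cgrid, params),
                    temperature_C = 25, ethanol_pct = 0)
  rep <- model_error(pts)
  expect_equal(rep$mae, 0)
  expect_equal(rep$mpe, 0)
  expect_equal(rep$direction, "unbiased")
})

test_that("model_error arithmetic and sign conventions", {
  params <- langmuir_parameters(condition(25, 0))
  cgrid <- c(300, 900)
  pred <- isotherm_q(cgrid, params)
  # both observations 0.05 below prediction, with q_obs pinned to 0.28
  shift <- pred - 0.28
  pts <- data.frame(c_mg_per_L = cgrid,
                    q_mg_per_mg = c(0.28, 0.28),
                    temperature_C = 25, ethanol_pct = 0)
  rep <- model_error(pts)
  expect_equal(rep$mae, mean(abs(shift)))
  expect_equal(rep$mpe, mean(abs(shift)) / 0.28 * 100)
  # synthetic magnitudes: two points off by 0.05 at q_obs = 0.28 -> 17.86 %
  expect_equal(0.05 / 0.28 * 100, 17.8571, tolerance = 1e-4)

  # overestimation labelled as such
  lo <- data.frame(c_mg_per_L = cgrid,
                   q_mg_per_mg = pred - 0.01,
                   temperature_C = 25, ethanol_pct = 0)
  expect_equal(model_error(lo)$direction, "overestimates")

  # q_obs = 0 excluded from percent error with a count
  z <- data.frame(c_mg_per_L = c(100, 500),
                  q_mg_per_mg = c(0, 0.2),
                  temperature_C = 25, ethanol_pct = 0)
  rz <- model_error(z)
  expect_equal(rz$n_excluded, 1L)
  expect_false(is.na(rz$mpe))
})

test_that("benchmark desorption table satisfies its own arithmetic", {
  ref <- reference_desorption()
  expect_equal(nrow(ref), 12L)
  expect_equal(desorption_fractions(15), c(0.2673, 0.3736, 0.4796))
  expect_error(desorption_fractions(5), "no measured")
  # within every ethanol level, mean desorption grows with temperature
  for (E in unique(ref$ethanol_pct)) {
    m <- ref$mean_pct[ref$ethanol_pct == E][order(ref$temperature_C[ref$ethanol_pct == E])]
    expect_true(all(diff(m) > 0))
  }
})
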