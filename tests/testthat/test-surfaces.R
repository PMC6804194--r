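test_that("evaluate_surface computes the rational form", {
  s <- rational_surface(numerator = c(const = 2), denominator = c(coef_T = 1))
  expect_equal(evaluate_surface(s, condition(2 - 273.15, 0)), 1.0)

  # hand-evaluated: (n0 + nT*T + nE*E) / (d0 + dT*T + dE*E + dTE*T*E)
  s2 <- rational_surface(numerator = c(const = 1, coef_T = 2, coef_E = 3),
                         denominator = c(const = 4, coef_T = 5, coef_E = 6,
                                         coef_TE = 7))
  T <- 300; E <- 10
  expect_equal(evaluate_surface(s2, condition(T - 273.15, E)),
               (1 + 2 * 300 + 3 * 10) / (4 + 5 * 300 + 6 * 10 + 7 * 3000))
})

test_that("as-printed coefficient set matches hand-evaluated values at 35 degC, 15 %", {
  # independent arithmetic: numerator/denominator evaluated term by term
  cs <- surface_coefficients("printed")
  cond <- condition(35, 15)
  k_expect <- (1.21e-3 - 2.69e-3 * 308.15) /
    (-9.01 * 308.15 - 1.25e2 * 15 + 308.15 * 15)
  s_expect <- (4.57e-1 + 2.04e1 * 15) /
    (-6.69 * 15 + 4.57e-1 * 308.15 + 308.15 * 15)
  expect_equal(evaluate_surface(cs$keq, cond), k_expect)
  expect_equal(evaluate_surface(cs$scwm, cond), s_expect)
  expect_equal(k_expect, 0.02836, tolerance = 2e-4)
  expect_equal(s_expect, 0.06573, tolerance = 2e-4)
})

test_that("default coefficient set matches hand-evaluated values", {
  cs <- surface_coefficients("default")
  k_expect <- (1.21e-3 - 2.69e3 * 308.15) /
    (-9.01 * 308.15 - 1.25e2 * 15 + 308.15 * 15)
  s_expect <- (4.57e1 + 2.04e1 * 15) /
    (-6.69 * 15 + 4.57e-1 * 308.15 + 308.15 * 15)
  expect_equal(evaluate_surface(cs$keq, condition(35, 15)), k_expect)
  expect_equal(evaluate_surface(cs$scwm, condition(35, 15)), s_expect)
  # at zero ethanol the default saturation surface is (45.7 + 0)/(0.457 T)
  expect_equal(evaluate_surface(cs$scwm, condition(15, 0)),
               45.7 / (0.457 * 288.15))
})

test_that("singular denominators raise a named error", {
  s <- rational_surface(numerator = c(const = 1),
                        denominator = c(const = -300, coef_T = 1),
                        label = "keq")
  expect_error(evaluate_surface(s, condition(300 - 273.15, 0)), "singular")
  # the default Keq denominator has a pole just above the calibrated corner
  cs <- surface_coefficients()
  d <- cs$keq$denominator
  T_pole <- 308.15
  E_pole <- -d[["coef_T"]] * T_pole / (d[["coef_E"]] + T_pole)
  expect_error(
    suppressWarnings(evaluate_surface(cs$keq, condition(35, E_pole), tol = 1e-6)),
    "singular")
})

test_that("langmuir_parameters composes the surfaces and flags extrapolation", {
  p <- langmuir_parameters(condition(35, 15))
  cs <- surface_coefficients()
  expect_equal(p$keq, evaluate_surface(cs$keq, condition(35, 15)))
  expect_equal(p$scwm, evaluate_surface(cs$scwm, condition(35, 15)))
  expect_false(p$extrapolated)

  # determinism
  p2 <- langmuir_parameters(condition(35, 15))
  expect_identical(p[c("keq", "scwm")], p2[c("keq", "scwm")])

  expect_warning(langmuir_parameters(condition(40, 0)), "envelope")
  expect_warning(langmuir_parameters(condition(10, 0)), "envelope")

  # user-override coefficients are honoured, not the defaults
  override <- list(
    keq = rational_surface(c(const = 10), c(const = 2), "keq"),
    scwm = rational_surface(c(const = 3), c(const = 10), "scwm"))
  po <- langmuir_parameters(condition(25, 0), override)
  expect_equal(po$keq, 5)
  expect_equal(po$scwm, 0.3)
})

test_that("non-positive surface values are rejected as unphysical", {
  bad <- list(keq = rational_surface(c(const = -1), c(const = 1), "keq"),
              scwm = rational_surface(c(const = 1), c(const = 1), "scwm"))
  expect_error(langmuir_parameters(condition(25, 0), bad), "not physically")
})

test_that("default surfaces are strictly positive over the calibrated grid", {
  cs <- surface_coefficients()
  for (E in c(0, 7.5, 12, 15)) {
    for (T_K in seq(288.15, 308.15, by = 0.5)) {
      cond <- condition(T_K - 273.15, E)
      expect_gt(evaluate_surface(cs$keq, cond), 0)
      expect_gt(evaluate_surface(cs$scwm, cond), 0)
    }
  }
})

test_that("conditions validate their domain", {
  expect_error(condition(-300, 0), "temperature")
  expect_error(condition(20, -1), "ethanol")
  expect_true(condition(40, 0)$extrapolated)
  expect_false(condition(15, 0)$extrapolated)
  expect_equal(condition(15, 0)$temperature_K, 288.15)
})
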