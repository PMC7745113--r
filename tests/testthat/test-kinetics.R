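test_that("rate constant follows the Arrhenius law exactly", {
  k40 <- rate_constant(313.15, default_cfg$kinetics)
  k10 <- rate_constant(283.15, default_cfg$kinetics)
  # direct evaluation of A exp(-Ea/RT) with the configured parameters
  expect_equal(k40, 2.0e8 * exp(-57930 / (8.314 * 313.15)))
  expect_equal(k10, 2.0e8 * exp(-57930 / (8.314 * 283.15)))
  expect_equal(k40, 4.34e-2, tolerance = 1e-2)
  # exact temperature-ratio identity
  expect_equal(k40 / k10, exp(-57930 / 8.314 * (1 / 313.15 - 1 / 283.15)))
  # Ea = 0 collapses to the pre-exponential at any temperature
  expect_equal(arrhenius_rate(300, 5, 0), 5)
  expect_equal(arrhenius_rate(400, 5, 0), 5)
  expect_error(arrhenius_rate(-10), "positive")
})

test_that("batch conversion matches its closed forms and is monotone", {
  expect_equal(batch_conversion(1, 1, 1, 1), 0.5) # k c0 t = 1
  expect_equal(batch_conversion(2, 2, 0.25, 0), 0)
  expect_equal(batch_conversion(1, 1.5, 0, 100), 0)
  t <- seq(0, 50, 0.5)
  x <- batch_conversion(1, 1.5, 0.1, t)
  expect_true(all(diff(x) >= 0))
  expect_true(all(x >= 0 & x < 1))
  expect_lt(batch_conversion(1, 1.5, 0.05, 10), batch_conversion(1, 1.5, 0.1, 10))
  expect_error(batch_conversion(1, 1, 1, -1), "nonnegative")
  expect_error(batch_conversion(0, 1, 1, 1), "positive")
})

test_that("batch conversion agrees with brute-force ODE integration", {
  skip_if_not_installed("deSolve")
  expect_equal(batch_conversion(1, 1.5, 0.1, 10), ode_conversion(1, 1.5, 0.1, 10),
               tolerance = 1e-6)
  set.seed(7)
  for (i in 1:100) {
    a0 <- runif(1, 0.2, 5)
    b0 <- runif(1, 0.2, 5)
    k <- runif(1, 0.001, 0.5)
    t <- runif(1, 0, 60)
    expect_equal(batch_conversion(a0, b0, k, t), ode_conversion(a0, b0, k, t),
                 tolerance = 1e-6)
  }
})

test_that("Arrhenius fitting recovers the generating parameters from noiseless curves", {
  curves <- simulate_batch_kinetics(
    c(283.15, 293.15, 303.15, 313.15), seq(0, 90, 3),
    kinetics = default_cfg$kinetics
  )
  fit <- fit_arrhenius(curves)
  expect_equal(fit$activation_energy, 57930, tolerance = 1e-3)
  expect_equal(fit$pre_exponential, 2.0e8, tolerance = 2e-2)
  expect_gt(fit$r_squared, 0.999999)
  g <- glance(fit)
  expect_identical(g$n_temperatures, 4L)
  expect_equal(nrow(tidy(fit)), 4L)

  # equal-feed series exercise the 1/c branch of the per-temperature fit
  eq <- simulate_batch_kinetics(c(288.15, 308.15), seq(0, 60, 2),
                                c_a0 = 1, c_b0 = 1,
                                kinetics = default_cfg$kinetics)
  fit_eq <- fit_arrhenius(eq)
  expect_equal(fit_eq$activation_energy, 57930, tolerance = 1e-3)
})

test_that("Arrhenius fitting guards its preconditions", {
  one_t <- simulate_batch_kinetics(303.15, seq(0, 60, 5))
  expect_error(fit_arrhenius(one_t), "two or more distinct temperatures")
  expect_error(fit_arrhenius(dplyr::select(one_t, -"conc_b")), "missing columns")

  wobbly <- simulate_batch_kinetics(c(293.15, 313.15), seq(0, 60, 5))
  wobbly$conc_a[3] <- wobbly$conc_a[2] * 1.05 # non-monotone blip
  expect_warning(fit <- fit_arrhenius(wobbly), "not monotone")
  expect_s3_class(fit, "arrhenius_fit")
})
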