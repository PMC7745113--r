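test_that("residence time follows pi r^2 L / Q", {
  expect_equal(residence_time(5, 1.0, 0.1), 39.27, tolerance = 1e-4)
  # hand evaluation for a short narrow reactor
  expect_equal(residence_time(1, 0.25, 1),
               pi * (0.125e-3)^2 * 1 / 1e-6, tolerance = 1e-12)
  expect_equal(residence_time(1, 0.25, 1), 0.0491, tolerance = 1e-3)
  # doubling the flow halves tau exactly
  expect_equal(residence_time(3, 0.5, 0.4), 2 * residence_time(3, 0.5, 0.8))
  expect_equal(residence_time(5, 1, 0.1, units = "s"),
               60 * residence_time(5, 1, 0.1))
  expect_error(residence_time(0, 1, 1), "positive")
})

test_that("inlet composition solves the neat-feed split", {
  # symmetric reagents at chi = 1 split the flow evenly
  cfg_sym <- flow_config(overrides = list(species = list(
    M4MAA = list(density = 1000, molar_mass = 0.1),
    DMF_DMA = list(density = 1000, molar_mass = 0.1)
  )))
  inl <- inlet_composition(1, 1, cfg_sym)
  expect_equal(inl$flow_rate, c(0.5, 0.5))
  expect_equal(inl$conc, c(5000, 5000))

  # chi -> 0 starves the second feed
  inl0 <- inlet_composition(1e-9, 1, default_cfg)
  expect_lt(inl0$flow_rate[2], 1e-8)
  expect_lt(inl0$conc[2], 1e-4)

  # algebraic oracle: root of the two-equation feed balance
  chi <- 1.5
  q <- 1
  a <- species_props(default_cfg, "reactant_a")
  b <- species_props(default_cfg, "reactant_b")
  f <- function(q1) (q - q1) * b$density / b$molar_mass - chi * q1 * a$density / a$molar_mass
  q1 <- uniroot(f, c(1e-12, q - 1e-12), tol = 1e-15)$root
  inl2 <- inlet_composition(chi, q, default_cfg)
  expect_equal(inl2$flow_rate[1], q1, tolerance = 1e-10)
  expect_equal(inl2$conc[1], q1 * 1e-6 * a$density / a$molar_mass / (q * 1e-6),
               tolerance = 1e-10)
  # molar ratio honoured; limiting reagent is A above chi = 1
  expect_equal(inl2$molar_flow[2] / inl2$molar_flow[1], chi)
  expect_true(inl2$limiting[1] && !inl2$limiting[2])
  expect_error(inlet_composition(-1, 1), "positive")
})

test_that("Reynolds and Peclet numbers match their definitions", {
  dn <- dimensionless_numbers(1, 1, density = 1000, viscosity = 5e-3,
                              diffusivity = 1e-9)
  expect_equal(dn$peclet, 2.12e4, tolerance = 1e-3)
  expect_equal(dn$reynolds, 4.24, tolerance = 1e-2)
  # halving ID at fixed Q quadruples u and doubles Pe
  dn2 <- dimensionless_numbers(0.5, 1, density = 1000, viscosity = 5e-3)
  expect_equal(dn2$u_bar, 4 * dn$u_bar)
  expect_equal(dn2$peclet, 2 * dn$peclet)
})

test_that("vanishing kinetics produce no yield and a bath-temperature outlet", {
  cfg0 <- flow_config(overrides = list(kinetics = list(pre_exponential = 1e-20)))
  sim <- solve_reactor_case(1, 0.5, 0.5, 40, 1.2, config = cfg0,
                            grid = coarse_grid)
  g <- glance(sim)
  expect_lt(g$yield_pct, 1e-8)
  expect_equal(g$outlet_temperature, 313.15, tolerance = 1e-4)
  # zero-kinetics diffusivity sweep: all yields zero
  sw <- diffusivity_sweep(1, 0.5, 0.5, 40, 1.2, c(1e-9, 1e-10),
                          config = cfg0, grid = coarse_grid)
  expect_true(all(sw$yield_pct < 1e-8))
  expect_equal(attr(sw, "spread"), 0, tolerance = 1e-8)
})

test_that("the radially well-mixed solver approaches the plug-flow oracle", {
  sim <- solve_reactor_case(2, 0.5, 0.2, 25, 1.2, config = default_cfg,
                            grid = c(coarse_grid, list(diffusivity = 1e-6,
                                                       energy_equation = FALSE)))
  inl <- sim$inlet
  k <- rate_constant(298.15, default_cfg$kinetics)
  ref <- pfr_yield(inl$conc[1] / 1000, inl$conc[2] / 1000, k,
                   residence_time(2, 0.5, 0.2))
  expect_lt(abs(glance(sim)$yield_pct - ref), 1) # within one percentage point
})

test_that("species are conserved and the energy balance stays bounded", {
  sim <- solve_reactor_case(3, 1, 0.4, 40, 0.95, config = default_cfg,
                            grid = coarse_grid, snapshot_multiples = 5)
  g <- glance(sim)
  expect_lt(g$conservation_rel_error, 0.005)
  # temperature bounded by inlet/bath plus the adiabatic rise
  temps <- sim$snapshots[[1]]$temperature
  kin <- default_cfg$kinetics
  rise <- -kin$heat_of_reaction * max(sim$inlet$conc) / sim$mixture$rho_cp
  expect_gte(min(temps), min(313.15, default_cfg$grid$inlet_temperature) - 1)
  expect_lte(max(temps), 313.15 + rise)
  # velocity profile: nonnegative, maximal on the axis, ~zero at the wall
  expect_true(all(sim$axial_velocity >= 0))
  expect_equal(which.max(sim$axial_velocity), 1L)
  expect_lt(sim$axial_velocity[length(sim$axial_velocity)],
            0.2 * max(sim$axial_velocity))
})

test_that("transient profiles start empty, reach steady state, and rise monotonically", {
  sim <- solve_reactor_case(2, 1, 0.5, 40, 0.95, config = default_cfg,
                            grid = coarse_grid)
  prof <- transient_profiles(sim, c(0, 0.5, 1, 5))
  p0 <- dplyr::filter(prof, multiple == 0)
  expect_true(all(p0$yield_pct == 0))
  # 5 tau snapshot equals the stored steady profile within the tolerance
  p5 <- dplyr::filter(prof, multiple == 5)
  final <- sim$yield_profiles[nrow(sim$yield_profiles), ]
  expect_equal(p5$yield_pct, final, tolerance = default_cfg$grid$steady_tolerance)
  # pointwise nondecreasing approach between 1 tau and 5 tau
  p1 <- dplyr::filter(prof, multiple == 1)
  expect_true(all(p5$yield_pct - p1$yield_pct > -1e-6))
  # yield along the length is nondecreasing at steady state
  expect_true(all(diff(final) > -1e-8))
  expect_error(transient_profiles(sim, 7), "outside the simulated time range")
})

test_that("case and grid validation reject unphysical setups", {
  expect_error(reactor_case(0.05, 1, 1, 25, 1), "aspect ratio")
  expect_error(reactor_case(1, 1, 1, 200, 1), "250-400")
  expect_error(grid_options(default_cfg, n_radial = 4), "n_radial >= 8")
  expect_error(grid_options(default_cfg, diffusivity = -1), "positive")
})

test_that("simulate_reactor flags failed cases and keeps going", {
  cases <- dplyr::bind_rows(
    reactor_case(1, 0.5, 0.5, 40, 1.2),
    reactor_case(1, 0.5, 0.5, 10, 0.95)
  )
  cases$T_C[2] <- -100 # invalid once solved
  expect_message(
    res <- simulate_reactor(cases, config = default_cfg, grid = coarse_grid),
    "failed"
  )
  expect_identical(res$failed, c(FALSE, TRUE))
  expect_true(is.na(res$yield_pct[2]))
  expect_gt(res$yield_pct[1], 0)
})
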