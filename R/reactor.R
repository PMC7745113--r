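#' Mean hydraulic residence time of a tube reactor
#'
#' \eqn{\tau = \pi (ID/2)^2 L / Q}: internal volume over volumetric flow.
#'
#' @param length Reactor length, m.
#' @param inner_diameter Inner diameter, mm.
#' @param flow_rate Total volumetric flow rate, mL min^-1.
#' @param units `"min"` (default) or `"s"`.
#' @return Residence time in the requested units.
#' @examples
#' residence_time(5, 1.0, 0.1) # 39.27 min
#' @export
residence_time <- function(length, inner_diameter, flow_rate, units = c("min", "s")) {
  units <- match.arg(units)
  if (any(length <= 0) || any(inner_diameter <= 0) || any(flow_rate <= 0)) {
    abort("length, inner_diameter and flow_rate must be positive")
  }
  area <- pi * (inner_diameter * 1e-3 / 2)^2            # m2
  tau_s <- area * length / (flow_rate * 1e-6 / 60)      # s
  if (units == "min") tau_s / 60 else tau_s
}

#' Inlet composition from two neat reagent feeds
#'
#' Two undiluted reagent streams (reactant A = M4MAA, reactant B = DMF-DMA)
#' meet at a tee and are treated as instantaneously mixed at the reactor
#' inlet.  Given the feed mole ratio \eqn{\chi} (B : A) and the total flow
#' `Q`, the stream split solves \eqn{F_j = Q_j \rho_j / M_j},
#' \eqn{F_B/F_A = \chi}, \eqn{Q_A + Q_B = Q}; inlet concentrations are
#' \eqn{c_j = F_j / Q}.
#'
#' @param chi Feed mole ratio B : A (> 0).
#' @param flow_rate Total flow rate, mL min^-1.
#' @param config A [flow_config()].
#' @return A tibble with one row per reactant: `species`, `flow_rate`
#'   (mL min^-1), `molar_flow` (mol min^-1), `conc` (mol m^-3), and a
#'   `limiting` flag (the reactant fed in molar deficit).
#' @examples
#' inlet_composition(0.95, 0.1)
#' @export
inlet_composition <- function(chi, flow_rate, config = flow_config()) {
  if (!is.finite(chi) || chi <= 0) abort("chi must be positive")
  if (!is.finite(flow_rate) || flow_rate <= 0) abort("flow_rate must be positive")
  a <- species_by_role(config, "reactant_a")
  b <- species_by_role(config, "reactant_b")
  ma <- a$density / a$molar_mass # molar density of neat A, mol m-3
  mb <- b$density / b$molar_mass
  gamma <- chi * ma / mb         # Q_B / Q_A
  q_a <- flow_rate / (1 + gamma)
  q_b <- flow_rate - q_a
  f_a <- q_a * 1e-6 * ma         # mol min-1
  f_b <- q_b * 1e-6 * mb
  q_si <- flow_rate * 1e-6       # m3 min-1
  tibble(
    species = c(a$name, b$name),
    flow_rate = c(q_a, q_b),
    molar_flow = c(f_a, f_b),
    conc = c(f_a, f_b) / q_si,
    limiting = if (chi < 1) c(FALSE, TRUE) else c(TRUE, FALSE)
  )
}

#' Reynolds and Peclet numbers of the tube flow
#'
#' \eqn{Re = \rho \bar{u} \, ID / \mu} and \eqn{Pe = \bar{u} \, ID / D}
#' with the superficial velocity \eqn{\bar{u} = Q / (\pi (ID/2)^2)}.
#'
#' @inheritParams residence_time
#' @param density Mixture density, kg m^-3.
#' @param viscosity Mixture dynamic viscosity, Pa s.
#' @param diffusivity Species diffusivity, m^2 s^-1.
#' @return A tibble with `u_bar` (m s^-1), `reynolds` and `peclet`.
#' @examples
#' dimensionless_numbers(1.0, 1, density = 1000, viscosity = 5e-3)
#' @export
dimensionless_numbers <- function(inner_diameter, flow_rate,
                                  density, viscosity, diffusivity = 1e-9) {
  check_positive(c(inner_diameter, flow_rate, density, viscosity, diffusivity),
                 "dimensionless_numbers inputs")
  id_m <- inner_diameter * 1e-3
  u_bar <- (flow_rate * 1e-6 / 60) / (pi * (id_m / 2)^2)
  tibble(
    u_bar = u_bar,
    reynolds = density * u_bar * id_m / viscosity,
    peclet = u_bar * id_m / diffusivity
  )
}

#' Define a reactor case (one row of the design space)
#'
#' @param length Reactor length, m.
#' @param inner_diameter Inner diameter, mm.
#' @param flow_rate Total flow rate, mL min^-1.
#' @param temperature Bath temperature, degC.
#' @param chi Feed mole ratio DMF-DMA : M4MAA.
#' @return A one-row tibble with columns `L_m`, `ID_mm`, `Q_mL_min`, `T_C`,
#'   `chi`.
#' @examples
#' reactor_case(5, 1.0, 0.1, 40, 0.95)
#' @export
reactor_case <- function(length, inner_diameter, flow_rate, temperature, chi) {
  if (length <= 0 || inner_diameter <= 0 || flow_rate <= 0 || chi <= 0) {
    abort("length, inner_diameter, flow_rate and chi must be positive")
  }
  if (length / (inner_diameter * 1e-3) < 100) {
    abort("aspect ratio L/ID must be at least 100 for the thin-tube model")
  }
  t_k <- temperature + 273.15
  if (t_k < 250 || t_k > 400) abort("temperature must lie within 250-400 K")
  tibble(L_m = length, ID_mm = inner_diameter, Q_mL_min = flow_rate,
         T_C = temperature, chi = chi)
}

#' Numerical grid and physics options for the axisymmetric solver
#'
#' Defaults come from the `grid` block of the configuration: 32 radial by
#' 400 axial cells, isotropic species diffusivity 1e-9 m^2 s^-1, the energy
#' balance enabled with organic-liquid thermal conductivity, integration to
#' five residence times.
#'
#' @param config A [flow_config()] providing defaults.
#' @param ... Named overrides of the grid block, e.g. `n_radial = 64`,
#'   `diffusivity = 1e-12`, `energy_equation = FALSE`.
#' @return The merged grid options list.
#' @export
grid_options <- function(config = flow_config(), ...) {
  g <- modify_list_deep(config$grid, list(...))
  if (g$n_radial < 8 || g$n_axial < 50) {
    abort("need n_radial >= 8 and n_axial >= 50")
  }
  if (g$diffusivity <= 0) abort("diffusivity must be positive")
  g
}

# inlet mixture properties (density, viscosity, volumetric heat capacity)
# evaluated at the unreacted feed composition
inlet_mixture <- function(inlet, config) {
  sp <- config$species[match(inlet$species, config$species$name), ]
  mass_flow <- inlet$molar_flow * sp$molar_mass
  w <- mass_flow / sum(mass_flow)
  n <- inlet$molar_flow / sum(inlet$molar_flow)
  rho <- mixture_density(w, sp$density)
  mu <- mixture_viscosity(n, sp$viscosity)
  cp_mass <- mixture_heat_capacity(w, sp$molar_heat_capacity, sp$molar_mass)
  list(density = rho, viscosity = mu, cp_mass = cp_mass,
       rho_cp = rho * cp_mass)
}

#' Solve one transient reactor case
#'
#' Integrates the 2-D axisymmetric convection-diffusion-reaction system
#' (plus, by default, the energy balance with Dirichlet wall temperature)
#' from an initial fill of reactant A decaying linearly to zero at the
#' outlet, out to `end_time_multiple` residence times.  Yields are
#' mixing-cup (flow-weighted) percentages of the limiting reagent.
#'
#' @inheritParams reactor_case
#' @param config A [flow_config()].
#' @param grid Grid options from [grid_options()] (or a named list of
#'   overrides applied to the config defaults).
#' @param snapshot_multiples Residence-time multiples at which full field
#'   snapshots are stored.
#' @param impurity Include the first-order product-consuming impurity
#'   channel of the pseudo-experiment configuration?
#' @param bath_offset Additive perturbation of the bath temperature, K
#'   (used by the pseudo-experiment generator).
#' @return An object of class `reactor_sim`; see [glance.reactor_sim()] for
#'   the summary row and [transient_profiles()] for axial yield snapshots.
#' @examples
#' \donttest{
#' sim <- solve_reactor_case(5, 1.0, 0.1, 40, 0.95,
#'   grid = list(n_radial = 16, n_axial = 100)
#' )
#' glance(sim)
#' }
#' @export
solve_reactor_case <- function(length, inner_diameter, flow_rate, temperature,
                               chi, config = flow_config(),
                               grid = grid_options(config),
                               snapshot_multiples = c(0, 0.5, 1, 2.5, 5),
                               impurity = FALSE, bath_offset = 0) {
  case <- reactor_case(length, inner_diameter, flow_rate, temperature, chi)
  if (!is.list(grid)) abort("grid must be a grid_options() list")
  grid <- modify_list_deep(config$grid, grid)

  tau_s <- residence_time(length, inner_diameter, flow_rate, units = "s")
  inlet <- inlet_composition(chi, flow_rate, config)
  mix <- inlet_mixture(inlet, config)
  id_m <- inner_diameter * 1e-3
  u_bar <- (flow_rate * 1e-6 / 60) / (pi * (id_m / 2)^2)
  t_bath <- temperature + 273.15 + bath_offset
  kin <- config$kinetics
  alpha <- grid$thermal_conductivity / mix$rho_cp

  syn <- config$synthetic_experiment
  k2a <- if (impurity) syn$impurity_pre_exponential else 0
  k2ea <- if (impurity) syn$impurity_activation_energy else 0

  c_a_in <- inlet$conc[1]
  c_b_in <- inlet$conc[2]
  c_lim <- inlet$conc[inlet$limiting]

  raw <- reactor_solve_cpp(
    L = length, radius = id_m / 2, ubar = u_bar,
    nr = as.integer(grid$n_radial), nz = as.integer(grid$n_axial),
    D = grid$diffusivity, alpha = alpha,
    energy_on = isTRUE(grid$energy_equation),
    cA_in = c_a_in, cB_in = c_b_in,
    T_in = grid$inlet_temperature, T_bath = t_bath,
    kA_si = kin$pre_exponential_si, kEa = kin$activation_energy,
    Rgas = kin$gas_constant %||% .R_GAS,
    k2A = k2a, k2Ea = k2ea,
    dH = kin$heat_of_reaction, rho_cp = mix$rho_cp,
    c_lim_in = c_lim,
    t_end = grid$end_time_multiple * tau_s,
    cfl = grid$cfl, n_save = as.integer(grid$n_save),
    snapshot_times = snapshot_multiples * tau_s
  )

  ss <- steady_state_multiple(raw$times, raw$yield_out, tau_s,
                              tol = grid$steady_tolerance)

  consumed <- c_lim - if (inlet$limiting[1]) raw$outlet$conc_a else raw$outlet$conc_b
  produced <- raw$outlet$conc_p + raw$outlet$conc_i
  cons_err <- abs(consumed - produced) / max(abs(consumed), 1e-30)

  dn <- dimensionless_numbers(inner_diameter, flow_rate, mix$density,
                              mix$viscosity, grid$diffusivity)

  structure(
    list(
      case = case, grid = grid, tau_s = tau_s, inlet = inlet, mixture = mix,
      times = raw$times, yield_vs_time = raw$yield_out,
      impurity_vs_time = raw$impurity_out,
      yield_profiles = raw$yield_profiles, z = raw$z, r = raw$r,
      axial_velocity = raw$axial_velocity,
      snapshots = raw$snapshots, snapshot_multiples = snapshot_multiples,
      outlet = raw$outlet, dimensionless = dn,
      steady = ss, conservation_rel_error = cons_err,
      n_steps = raw$n_steps, dt = raw$dt,
      byproduct_stoichiometry = kin$byproduct_stoichiometry %||% 2
    ),
    class = "reactor_sim"
  )
}

# earliest saved residence-time multiple after which the outlet yield stays
# within `tol` (relative) of the final value through the end of the run
steady_state_multiple <- function(times, yields, tau_s, tol = 0.01) {
  y_end <- yields[length(yields)]
  denom <- max(abs(y_end), 1e-12)
  ok <- rev(cumprod(rev(abs(yields - y_end) / denom <= tol))) == 1
  idx <- which(ok)[1]
  list(
    multiple = times[idx] / tau_s,
    reached = !is.na(idx) && times[idx] < times[length(times)],
    final_yield = y_end
  )
}

#' @export
print.reactor_sim <- function(x, ...) {
  g <- glance(x)
  cat("<reactor_sim>\n")
  cat(sprintf("  case: L = %g m, ID = %g mm, Q = %g mL/min, T = %g C, chi = %g\n",
              g$L_m, g$ID_mm, g$Q_mL_min, g$T_C, g$chi))
  cat(sprintf("  tau = %.3g min, Re = %.3g, Pe = %.3g\n",
              g$tau_min, g$reynolds, g$peclet))
  cat(sprintf("  outlet yield = %.2f%% (steady after %.2f tau)\n",
              g$yield_pct, g$steady_multiple))
  invisible(x)
}

#' Summarise a reactor simulation as one tibble row
#'
#' @param x A `reactor_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: the case definition, `tau_min`, `yield_pct`,
#'   `impurity_pct`, `reynolds`, `peclet`, `steady_multiple` (residence-time
#'   multiples to steady state), `steady_ok`, `conservation_rel_error` and
#'   the outlet mixing-cup temperature (K).
#' @export
glance.reactor_sim <- function(x, ...) {
  n <- length(x$yield_vs_time)
  dplyr::bind_cols(
    x$case,
    tibble(
      tau_min = x$tau_s / 60,
      yield_pct = x$yield_vs_time[n],
      impurity_pct = x$impurity_vs_time[n],
      reynolds = x$dimensionless$reynolds,
      peclet = x$dimensionless$peclet,
      steady_multiple = x$steady$multiple,
      steady_ok = x$steady$reached,
      conservation_rel_error = x$conservation_rel_error,
      outlet_temperature = x$outlet$temperature
    )
  )
}

#' @export
tidy.reactor_sim <- function(x, ...) {
  tibble(
    time = x$times,
    multiple = x$times / x$tau_s,
    yield_pct = x$yield_vs_time,
    impurity_pct = x$impurity_vs_time
  )
}

#' Run a batch of reactor cases
#'
#' Vectorised front end to [solve_reactor_case()]: takes a tibble of cases
#' (columns `L_m`, `ID_mm`, `Q_mL_min`, `T_C`, `chi`, as produced by
#' [reactor_case()] or [build_design()]) and returns one summary row per
#' case.  Per-case solver failures are caught, reported, and returned as
#' `NA` rows so a campaign continues.
#'
#' @param cases A data frame of cases.
#' @param config A [flow_config()].
#' @param grid Grid options (see [solve_reactor_case()]).
#' @param impurity,bath_offset Passed to [solve_reactor_case()].
#' @param quiet Suppress the per-case progress message?
#' @return A tibble with the columns of [glance.reactor_sim()] plus `failed`.
#' @export
simulate_reactor <- function(cases, config = flow_config(),
                             grid = grid_options(config),
                             impurity = FALSE, bath_offset = 0,
                             quiet = TRUE) {
  req <- c("L_m", "ID_mm", "Q_mL_min", "T_C", "chi")
  missing <- setdiff(req, names(cases))
  if (length(missing) > 0) {
    abort(paste0("cases is missing columns: ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    out <- tryCatch(
      {
        sim <- solve_reactor_case(row$L_m, row$ID_mm, row$Q_mL_min, row$T_C,
                                  row$chi, config = config, grid = grid,
                                  snapshot_multiples = numeric(0),
                                  impurity = impurity,
                                  bath_offset = bath_offset)
        dplyr::mutate(glance(sim), failed = FALSE)
      },
      error = function(e) {
        message(sprintf("case %d failed: %s", i, conditionMessage(e)))
        dplyr::mutate(row, tau_min = residence_time(row$L_m, row$ID_mm, row$Q_mL_min),
                      yield_pct = NA_real_, impurity_pct = NA_real_,
                      reynolds = NA_real_, peclet = NA_real_,
                      steady_multiple = NA_real_, steady_ok = NA,
                      conservation_rel_error = NA_real_,
                      outlet_temperature = NA_real_, failed = TRUE)
      }
    )
    if (!quiet) {
      message(sprintf("case %d/%d: yield %.2f%%", i, nrow(cases), out$yield_pct))
    }
    out
  })
}

#' Axial yield profiles at selected residence-time multiples
#'
#' Extracts mixing-cup yield along the reactor length at the requested
#' startup times (fractions/multiples of the residence time), interpolating
#' between the stored profile times.
#'
#' @param sim A `reactor_sim`.
#' @param multiples Residence-time multiples within the simulated range.
#' @return A tibble with `multiple`, `time` (s), `z` (m), `yield_pct`.
#' @export
transient_profiles <- function(sim, multiples = c(0, 0.5, 1, 5)) {
  t_req <- multiples * sim$tau_s
  t_max <- sim$times[length(sim$times)]
  if (any(t_req < 0) || any(t_req > t_max * (1 + 1e-9))) {
    abort("requested multiples fall outside the simulated time range")
  }
  purrr::map_dfr(seq_along(multiples), function(k) {
    tk <- min(t_req[k], t_max)
    i2 <- which(sim$times >= tk - 1e-12)[1]
    i1 <- if (i2 == 1) 1 else i2 - 1
    f <- if (i2 == i1) 0 else (tk - sim$times[i1]) / (sim$times[i2] - sim$times[i1])
    prof <- (1 - f) * sim$yield_profiles[i1, ] + f * sim$yield_profiles[i2, ]
    tibble(multiple = multiples[k], time = tk, z = sim$z, yield_pct = prof)
  })
}

#' Sensitivity of outlet yield to the diffusion coefficient
#'
#' Re-solves one case over a set of isotropic diffusivities and reports the
#' outlet yield for each, plus the max-min spread.  A spread below a couple
#' of percentage points indicates a kinetically limited (not mass-transfer
#' limited) regime.
#'
#' @inheritParams solve_reactor_case
#' @param diffusivities Diffusivities to sweep, m^2 s^-1 (>= 1 value).
#' @return A tibble `diffusivity`, `yield_pct` with attribute `spread`
#'   (percentage points, max - min over successful runs).
#' @export
diffusivity_sweep <- function(length, inner_diameter, flow_rate, temperature,
                              chi, diffusivities,
                              config = flow_config(),
                              grid = grid_options(config), ...) {
  if (base::length(diffusivities) < 1) abort("need at least one diffusivity")
  out <- purrr::map_dfr(diffusivities, function(d) {
    y <- tryCatch(
      {
        g <- modify_list_deep(grid, list(diffusivity = d))
        sim <- solve_reactor_case(length, inner_diameter, flow_rate,
                                  temperature, chi, config = config,
                                  grid = g, snapshot_multiples = numeric(0), ...)
        glance(sim)$yield_pct
      },
      error = function(e) {
        message(sprintf("D = %g failed: %s", d, conditionMessage(e)))
        NA_real_
      }
    )
    tibble(diffusivity = d, yield_pct = y)
  })
  ok <- out$yield_pct[!is.na(out$yield_pct)]
  attr(out, "spread") <- if (length(ok) > 0) max(ok) - min(ok) else NA_real_
  out
}

#' Long-format field snapshots of a simulation
#'
#' @param sim A `reactor_sim` solved with non-empty `snapshot_multiples`.
#' @return A tibble `time` (s), `r` (m), `z` (m), `species`, `conc`
#'   (mol m^-3; `temperature` rows are in K).  The methanol byproduct is
#'   reported as its stoichiometric equivalent of everything ever produced,
#'   `2 * (Enamine + Impurity)`, which closes the mass balance exactly.
#' @export
field_snapshots <- function(sim) {
  if (length(sim$snapshots) == 0) {
    abort("simulation was run without field snapshots")
  }
  purrr::map_dfr(sim$snapshots, function(s) {
    grids <- expand.grid(r = sim$r, z = sim$z)
    meoh <- sim$byproduct_stoichiometry * (s$conc_p + s$conc_i)
    purrr::map_dfr(
      list(M4MAA = s$conc_a, DMF_DMA = s$conc_b, Enamine = s$conc_p,
           Impurity = s$conc_i, MeOH = meoh, temperature = s$temperature),
      function(m) tibble(time = s$time, r = grids$r, z = grids$z,
                         conc = as.vector(m)),
      .id = "species"
    )
  })
}
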