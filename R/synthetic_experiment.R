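#' Effective bath temperature of the pseudo-experimental campaign
#'
#' The pseudo-experiment emulates imperfect water-bath heating with a
#' constant bias plus a gradient term: a configured fraction of the
#' bath-ambient temperature difference is assumed lost across the coil, and
#' the solver (which has a single wall temperature) is run at the
#' coil-average value.  The perturbation in kelvin is
#' `bias + gradient_fraction * (ambient - bath) / 2`.
#'
#' @param temperature Nominal bath temperature, degC.
#' @param config A [flow_config()]; uses its `synthetic_experiment` block.
#' @return The bath offset in K to apply to the nominal temperature.
#' @export
bath_temperature_offset <- function(temperature, config = flow_config()) {
  syn <- config$synthetic_experiment
  t_bath <- temperature + 273.15
  syn$bath_bias + syn$bath_gradient_fraction * (syn$ambient_temperature - t_bath) / 2
}

#' Impurity abundance predicted for one condition
#'
#' Runs the reactor with the product-consuming side channel
#' (Enamine -> Impurity, first order in Enamine with its own Arrhenius
#' pair) enabled, and returns the outlet impurity level as a percentage of
#' the limiting reagent.  The mechanism of the real impurity is unknown;
#' this consecutive-reaction stand-in is tuned so the channel is negligible
#' at short residence times and reaches the low-percent range for long, hot
#' runs.
#'
#' @inheritParams solve_reactor_case
#' @return Impurity yield, percent of the limiting reagent.
#' @export
impurity_fraction <- function(length, inner_diameter, flow_rate, temperature,
                              chi, config = flow_config(),
                              grid = grid_options(config)) {
  sim <- solve_reactor_case(length, inner_diameter, flow_rate, temperature,
                            chi, config = config, grid = grid,
                            snapshot_multiples = numeric(0), impurity = TRUE)
  glance(sim)$impurity_pct
}

#' Generate a pseudo-experimental triplicate campaign
#'
#' Stands in for an HPLC-assayed experimental campaign: every design
#' condition is solved with (1) the bath perturbed by
#' [bath_temperature_offset()], (2) the impurity side channel enabled, then
#' (3) per-replicate multiplicative lognormal noise (coefficient of
#' variation `replicate_noise_cv`) applied to the yield.  The campaign is
#' deterministic for a fixed seed.
#'
#' @param design A design tibble from [build_design()] (typically the 16-run
#'   fraction); its `replicate` column is ignored in favour of the
#'   configured replicate count.
#' @param config A [flow_config()]; the `synthetic_experiment` block sets
#'   the impurity kinetics, bath imperfection, noise level and replicates.
#' @param grid Grid options for the underlying solver.
#' @param seed Integer seed for the replicate noise.
#' @param quiet Suppress progress messages?
#' @return A tibble with one row per condition x replicate: the design
#'   columns, `replicate`, `tau_min`, `yield_pct` (noisy), `impurity_pct`,
#'   `yield_noise_free`, `noise_factor` and `failed`.
#' @export
generate_campaign <- function(design, config = flow_config(),
                              grid = grid_options(config), seed = 1,
                              quiet = TRUE) {
  syn <- config$synthetic_experiment
  conditions <- dplyr::distinct(
    design, dplyr::across(dplyr::all_of(c("run", "A", "B", "C", "D", "E",
                                          "L_m", "ID_mm", "Q_mL_min", "T_C", "chi")))
  )
  n_rep <- max(1L, as.integer(syn$replicates))
  cv <- syn$replicate_noise_cv
  if (cv < 0) abort("replicate_noise_cv must be nonnegative")

  base <- purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    res <- tryCatch(
      {
        sim <- solve_reactor_case(
          row$L_m, row$ID_mm, row$Q_mL_min, row$T_C, row$chi,
          config = config, grid = grid, snapshot_multiples = numeric(0),
          impurity = TRUE,
          bath_offset = bath_temperature_offset(row$T_C, config)
        )
        g <- glance(sim)
        tibble(tau_min = g$tau_min, yield_noise_free = g$yield_pct,
               impurity_pct = g$impurity_pct, failed = FALSE)
      },
      error = function(e) {
        message(sprintf("condition %d failed and is excluded: %s",
                        i, conditionMessage(e)))
        tibble(tau_min = residence_time(row$L_m, row$ID_mm, row$Q_mL_min),
               yield_noise_free = NA_real_, impurity_pct = NA_real_,
               failed = TRUE)
      }
    )
    if (!quiet) message(sprintf("condition %d/%d done", i, nrow(conditions)))
    dplyr::bind_cols(row, res)
  })

  # lognormal multiplicative noise with unit mean, drawn reproducibly in
  # condition-major order
  sigma <- sqrt(log(1 + cv^2))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  draws <- if (cv > 0) {
    exp(rnorm(nrow(base) * n_rep, mean = -sigma^2 / 2, sd = sigma))
  } else {
    rep(1, nrow(base) * n_rep)
  }

  out <- tidyr::crossing(base, replicate = seq_len(n_rep))
  out <- dplyr::arrange(out, .data$run, .data$replicate)
  out$noise_factor <- draws
  out$seed <- as.integer(seed)
  out$yield_pct <- pmin(out$yield_noise_free * out$noise_factor,
                        100 - out$impurity_pct)
  n_failed <- sum(out$failed) / n_rep
  out <- dplyr::filter(out, !.data$failed)
  out <- dplyr::select(
    out, dplyr::all_of(c(
      "run", "A", "B", "C", "D", "E", "L_m", "ID_mm", "Q_mL_min", "T_C",
      "chi", "replicate", "tau_min", "yield_pct", "impurity_pct",
      "yield_noise_free", "noise_factor", "seed", "failed"
    ))
  )
  attr(out, "n_failed_conditions") <- n_failed
  out
}
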