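#' Run the full-factorial simulator campaign
#'
#' Solves the 32-run full \eqn{2^5} design with the deterministic reactor
#' simulator (no impurity channel, nominal bath) and returns the design
#' joined with per-run yields - the in-silico arm of the screening study.
#'
#' @param config A [flow_config()].
#' @param grid Grid options for the solver.
#' @param quiet Suppress per-case progress messages?
#' @return A design tibble with the [simulate_reactor()] summary columns.
#' @export
run_cfd_campaign <- function(config = flow_config(),
                             grid = grid_options(config), quiet = TRUE) {
  design <- build_design(default_factor_table(config), kind = "full")
  res <- simulate_reactor(design, config = config, grid = grid, quiet = quiet)
  dplyr::bind_cols(design[c("run", "A", "B", "C", "D", "E", "replicate")],
                   res[setdiff(names(res), "replicate")])
}

#' Run the pseudo-experimental fractional campaign
#'
#' Generates the triplicate 16-condition half-fraction campaign (48 records
#' by default) with [generate_campaign()].
#'
#' @inheritParams run_cfd_campaign
#' @param seed Seed for the replicate noise.
#' @return See [generate_campaign()].
#' @export
run_experiment_campaign <- function(config = flow_config(),
                                    grid = grid_options(config), seed = 1,
                                    quiet = TRUE) {
  design <- build_design(default_factor_table(config), kind = "fractional")
  generate_campaign(design, config = config, grid = grid, seed = seed,
                    quiet = quiet)
}

#' Read or write campaign tables as CSV
#'
#' Thin wrappers around readr with the fixed column conventions of this
#' package (units embedded in the column names: `L_m`, `ID_mm`, `Q_mL_min`,
#' `T_C`, `tau_min`, `yield_pct`).
#'
#' @param x A campaign or runs tibble.
#' @param path File path.
#' @return `write_runs_csv()` returns `x` invisibly; `read_runs_csv()`
#'   returns a tibble.
#' @export
write_runs_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_runs_csv
#' @export
read_runs_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(out) == 0) abort(paste0("no data rows in ", path))
  out
}
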