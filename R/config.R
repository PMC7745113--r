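#' Load the pipeline configuration
#'
#' Reads the packaged YAML configuration (species properties, kinetic
#' parameters, factor ranges, grid defaults and the pseudo-experiment block)
#' and applies any overrides.  All values are converted to SI once here, so
#' downstream code never mixes unit systems: the Arrhenius pre-exponential is
#' stored both as printed (L mol^-1 min^-1) and in SI (m^3 mol^-1 s^-1).
#'
#' @param path Path to a YAML configuration; defaults to the packaged
#'   `default_config.yaml`.
#' @param overrides Named list merged (recursively) over the file contents,
#'   e.g. `list(kinetics = list(activation_energy = 60000))`.
#' @return A list of class `flow_config` with elements `species` (a tibble),
#'   `kinetics`, `factors`, `grid` and `synthetic_experiment`.
#' @examples
#' cfg <- flow_config()
#' cfg$kinetics$activation_energy
#' @export
flow_config <- function(path = NULL, overrides = list()) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "flowreactor")
  }
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  raw <- modify_list_deep(raw, overrides)
  validate_config(raw)

  species <- purrr::imap_dfr(raw$species, function(sp, nm) {
    tibble(
      name = nm, role = sp$role,
      density = sp$density, viscosity = sp$viscosity,
      molar_heat_capacity = sp$molar_heat_capacity,
      molar_mass = sp$molar_mass
    )
  })

  kin <- raw$kinetics
  kin$pre_exponential_si <- kin$pre_exponential * 1e-3 / 60 # L/mol/min -> m3/mol/s

  structure(
    list(
      species = species,
      kinetics = kin,
      factors = raw$factors,
      grid = raw$grid,
      synthetic_experiment = raw$synthetic_experiment
    ),
    class = "flow_config"
  )
}

#' @export
print.flow_config <- function(x, ...) {
  cat("<flow_config>\n")
  cat("  species:", paste(x$species$name, collapse = ", "), "\n")
  cat(sprintf(
    "  kinetics: A = %.3g L mol-1 min-1, Ea = %.4g kJ mol-1\n",
    x$kinetics$pre_exponential, x$kinetics$activation_energy / 1000
  ))
  cat(sprintf(
    "  grid: %d x %d cells, D = %.1e m2 s-1, energy %s\n",
    x$grid$n_radial, x$grid$n_axial, x$grid$diffusivity,
    if (isTRUE(x$grid$energy_equation)) "on" else "off"
  ))
  invisible(x)
}

# recursive list merge; `new` wins, scalars replace, lists recurse
modify_list_deep <- function(base, new) {
  if (length(new) == 0) return(base)
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(raw) {
  need <- c("species", "kinetics", "factors", "grid", "synthetic_experiment")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("configuration is missing blocks: ", paste(missing, collapse = ", ")))
  }
  for (nm in names(raw$species)) {
    sp <- raw$species[[nm]]
    vals <- c(sp$density, sp$viscosity, sp$molar_heat_capacity, sp$molar_mass)
    if (length(vals) != 4 || any(!is.finite(vals)) || any(vals <= 0)) {
      abort(paste0("species '", nm, "' must have strictly positive density, ",
                   "viscosity, molar_heat_capacity and molar_mass"))
    }
  }
  kin <- raw$kinetics
  if (kin$pre_exponential <= 0 || kin$activation_energy <= 0) {
    abort("kinetics: pre_exponential and activation_energy must be positive")
  }
  for (f in names(raw$factors)) {
    rng <- raw$factors[[f]]
    if (!(rng$low < rng$high)) {
      abort(paste0("factor '", f, "': low must be below high"))
    }
  }
  g <- raw$grid
  if (g$n_radial < 8 || g$n_axial < 50) {
    abort("grid: need n_radial >= 8 and n_axial >= 50")
  }
  if (g$diffusivity <= 0) abort("grid: diffusivity must be positive")
  invisible(raw)
}

# role lookup helpers -------------------------------------------------------

#' Look up the properties of one species by its role
#'
#' @param config A [flow_config()].
#' @param role One of `"reactant_a"`, `"reactant_b"`, `"product"`,
#'   `"byproduct"`, `"impurity"`.
#' @return The matching one-row species tibble.
#' @export
species_props <- function(config, role) {
  species_by_role(config, role)
}

species_by_role <- function(config, role) {
  i <- which(config$species$role == role)
  if (length(i) != 1) {
    abort(paste0("configuration must define exactly one species with role '", role, "'"))
  }
  config$species[i, ]
}
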