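#' Ideal-solution mixture property rules
#'
#' Mixture relations used throughout the reactor model:
#' density by ideal specific-volume additivity
#' \eqn{1/\bar\rho = \sum_i w_i/\rho_i}, viscosity by the log-linear
#' (Arrhenius) mixing rule \eqn{\bar\mu = \exp(\sum_i n_i \ln \mu_i)}, and
#' the mass-specific heat capacity \eqn{\bar C_p = \sum_i c_{p,i} w_i / M_i}
#' built from molar heat capacities.
#'
#' `mass_fractions`/`mole_fractions` must be nonnegative and sum to 1 within
#' 1e-9.  All property vectors must be strictly positive and the same length
#' as the fraction vector.
#'
#' @param mass_fractions,mole_fractions Numeric composition vectors.
#' @param densities Species densities, kg m^-3.
#' @param viscosities Species dynamic viscosities, Pa s.
#' @param molar_heat_capacities Species molar heat capacities, J mol^-1 K^-1.
#' @param molar_masses Species molar masses, kg mol^-1.
#' @return A scalar mixture property: kg m^-3, Pa s, or J kg^-1 K^-1.
#' @examples
#' mixture_density(c(0.5, 0.5), c(1000, 500)) # harmonic, 666.67
#' mixture_viscosity(c(0.5, 0.5), c(1e-3, 4e-3)) # geometric, 2e-3
#' @name mixture-rules
NULL

#' @rdname mixture-rules
#' @export
mixture_density <- function(mass_fractions, densities) {
  check_fractions(mass_fractions, "mass_fractions")
  check_positive(densities, "densities", length(mass_fractions))
  1 / sum(mass_fractions / densities)
}

#' @rdname mixture-rules
#' @export
mixture_viscosity <- function(mole_fractions, viscosities) {
  check_fractions(mole_fractions, "mole_fractions")
  check_positive(viscosities, "viscosities", length(mole_fractions))
  exp(sum(mole_fractions * log(viscosities)))
}

#' @rdname mixture-rules
#' @export
mixture_heat_capacity <- function(mass_fractions, molar_heat_capacities, molar_masses) {
  check_fractions(mass_fractions, "mass_fractions")
  check_positive(molar_heat_capacities, "molar_heat_capacities", length(mass_fractions))
  check_positive(molar_masses, "molar_masses", length(mass_fractions))
  sum(molar_heat_capacities * mass_fractions / molar_masses)
}

#' Convert between mass and mole fractions
#'
#' @param w,n Mass / mole fraction vectors (sum to 1).
#' @param molar_masses Species molar masses, kg mol^-1.
#' @return The converted fraction vector.
#' @export
mass_to_mole_fractions <- function(w, molar_masses) {
  check_fractions(w, "w")
  check_positive(molar_masses, "molar_masses", length(w))
  n <- (w / molar_masses) / sum(w / molar_masses)
  n
}

#' @rdname mass_to_mole_fractions
#' @export
mole_to_mass_fractions <- function(n, molar_masses) {
  check_fractions(n, "n")
  check_positive(molar_masses, "molar_masses", length(n))
  (n * molar_masses) / sum(n * molar_masses)
}

check_fractions <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x))) {
    abort(paste0(what, " must be a finite numeric vector"))
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    abort(paste0(what, " must lie in [0, 1]"))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(paste0(what, " must sum to 1 (got ", format(sum(x), digits = 12), ")"))
  }
  invisible(x)
}

check_positive <- function(x, what, n = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0(what, " must be strictly positive"))
  }
  if (!is.null(n) && length(x) != n) {
    abort(paste0(what, " must have length ", n))
  }
  invisible(x)
}
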