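#' Arrhenius rate constant
#'
#' \eqn{k(T) = A \exp(-E_a / (R T))} for the second-order (first order in
#' each reactant) enamine condensation.  Units of `k` follow the
#' pre-exponential: the configuration default is L mol^-1 min^-1.
#'
#' @param temperature Absolute temperature(s), K.
#' @param pre_exponential Pre-exponential factor `A` (default config value,
#'   L mol^-1 min^-1).
#' @param activation_energy Activation energy `Ea`, J mol^-1.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return Rate constant(s) in the units of `pre_exponential`.
#' @examples
#' arrhenius_rate(313.15) # approx 4.3e-2 L/mol/min
#' @export
arrhenius_rate <- function(temperature,
                           pre_exponential = 2.0e8,
                           activation_energy = 57930,
                           gas_constant = 8.314) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("temperature must be positive (K)")
  }
  if (pre_exponential <= 0 || activation_energy < 0) {
    abort("pre_exponential must be > 0 and activation_energy >= 0")
  }
  pre_exponential * exp(-activation_energy / (gas_constant * temperature))
}

#' @rdname arrhenius_rate
#' @param kinetics The `kinetics` block of a [flow_config()].
#' @export
rate_constant <- function(temperature, kinetics = flow_config()$kinetics) {
  arrhenius_rate(
    temperature,
    pre_exponential = kinetics$pre_exponential,
    activation_energy = kinetics$activation_energy,
    gas_constant = kinetics$gas_constant %||% .R_GAS
  )
}

#' Closed-form batch conversion for second-order kinetics
#'
#' Fractional conversion of the limiting reagent in an isothermal batch
#' reaction \eqn{A + B \to} products with rate \eqn{k c_A c_B}.  For equal
#' feeds the integrated law gives \eqn{X = k c_0 t / (1 + k c_0 t)}; for
#' unequal feeds the standard integrated second-order law
#' \eqn{\ln\left(\frac{c_B c_{A0}}{c_A c_{B0}}\right) = (c_{B0}-c_{A0}) k t}
#' is solved for the limiting-reagent conversion.
#'
#' @param c_a0,c_b0 Initial concentrations, mol L^-1 (both > 0).
#' @param k Rate constant, L mol^-1 min^-1 (>= 0).
#' @param t Time(s), min (>= 0); vectorised.
#' @return Conversion(s) in `[0, 1)`, nondecreasing in `t` and `k`.
#' @examples
#' batch_conversion(1, 1, 1, 1) # k c0 t = 1 -> 0.5
#' @export
batch_conversion <- function(c_a0, c_b0, k, t) {
  if (!is.finite(c_a0) || !is.finite(c_b0) || c_a0 <= 0 || c_b0 <= 0) {
    abort("c_a0 and c_b0 must be positive")
  }
  if (!is.finite(k) || k < 0) abort("k must be nonnegative")
  if (any(!is.finite(t)) || any(t < 0)) abort("t must be nonnegative")
  if (k == 0) return(rep(0, length(t)))

  dc <- c_b0 - c_a0
  if (abs(dc) <= 1e-8 * max(c_a0, c_b0)) {
    c0 <- (c_a0 + c_b0) / 2
    x <- k * c0 * t / (1 + k * c0 * t)
  } else {
    # c_A(t) for the unequal-feed integrated law; c_B = c_A + (c_B0 - c_A0)
    e <- exp(dc * k * t)
    c_a <- c_a0 * dc / (c_b0 * e - c_a0)
    x <- if (c_a0 <= c_b0) 1 - c_a / c_a0 else 1 - (c_a + dc) / c_b0
  }
  pmin(pmax(x, 0), 1)
}

#' Simulate noiseless isothermal batch concentration-time curves
#'
#' Generates exact concentration-time series from the integrated
#' second-order rate law at one or more bath temperatures, as monitored in a
#' kinetic study.  The output feeds [fit_arrhenius()] for round-trip
#' parameter recovery.
#'
#' @param temperatures Bath temperatures, K.
#' @param times Sampling times, min (should start at 0).
#' @param c_a0,c_b0 Initial concentrations, mol L^-1.
#' @param kinetics Kinetics block of a [flow_config()].
#' @return A tibble with columns `temperature` (K), `time` (min), `conc_a`,
#'   `conc_b` (mol L^-1).
#' @examples
#' curves <- simulate_batch_kinetics(c(283.15, 313.15), seq(0, 60, 5))
#' @export
simulate_batch_kinetics <- function(temperatures,
                                    times,
                                    c_a0 = 1.0,
                                    c_b0 = 1.3,
                                    kinetics = flow_config()$kinetics) {
  purrr::map_dfr(temperatures, function(temp) {
    k <- rate_constant(temp, kinetics)
    x <- batch_conversion(c_a0, c_b0, k, times)
    xi <- x * min(c_a0, c_b0) # extent, mol/L
    tibble(
      temperature = temp, time = times,
      conc_a = c_a0 - xi, conc_b = c_b0 - xi
    )
  })
}

#' Fit Arrhenius parameters from batch concentration-time series
#'
#' Two-stage estimation mirroring standard kinetic analysis: (1) at each
#' temperature the rate constant is estimated by least squares on the
#' integrated second-order law (regressing \eqn{\ln(c_B/c_A)} on time for
#' unequal feeds, or \eqn{1/c_A} on time for equal feeds); (2) \eqn{\ln k}
#' is regressed on \eqn{1/T}, giving slope \eqn{-E_a/R} and intercept
#' \eqn{\ln A}.
#'
#' @param data A data frame with columns `temperature` (K), `time` (min),
#'   `conc_a` and `conc_b` (mol L^-1); at least two distinct temperatures,
#'   each series starting at time zero.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return An object of class `arrhenius_fit` with components
#'   `rate_constants` (tibble of per-temperature `k`), `activation_energy`
#'   (J mol^-1), `pre_exponential` (L mol^-1 min^-1), and the underlying
#'   Arrhenius-line `lm` fit.  Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' curves <- simulate_batch_kinetics(seq(283.15, 313.15, 10), seq(0, 90, 3))
#' fit <- fit_arrhenius(curves)
#' glance(fit)
#' @export
fit_arrhenius <- function(data, gas_constant = 8.314) {
  req <- c("temperature", "time", "conc_a", "conc_b")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    abort(paste0("data is missing columns: ", paste(missing, collapse = ", ")))
  }
  temps <- sort(unique(data$temperature))
  if (length(temps) < 2) {
    abort("need series at two or more distinct temperatures to fit an Arrhenius line")
  }

  rates <- purrr::map_dfr(temps, function(temp) {
    d <- dplyr::arrange(dplyr::filter(data, .data$temperature == temp), .data$time)
    if (any(d$conc_a <= 0) || any(d$conc_b <= 0)) {
      abort("concentrations must be strictly positive")
    }
    if (is.unsorted(rev(d$conc_a), strictly = FALSE)) {
      warn(sprintf(
        "concentration series at %.2f K is not monotone nonincreasing; fitting anyway",
        temp
      ))
    }
    a0 <- d$conc_a[1]
    b0 <- d$conc_b[1]
    if (abs(b0 - a0) > 1e-8 * max(a0, b0)) {
      sl <- unname(coef(lm(log(d$conc_b / d$conc_a) ~ d$time))[2])
      k <- sl / (b0 - a0)
    } else {
      k <- unname(coef(lm(I(1 / d$conc_a) ~ d$time))[2])
    }
    tibble(temperature = temp, k = k, n_points = nrow(d))
  })
  if (any(rates$k <= 0)) {
    abort("estimated a non-positive rate constant; check the input series")
  }

  line <- lm(log(k) ~ I(1 / temperature), data = rates)
  slope <- unname(coef(line)[2])
  intercept <- unname(coef(line)[1])
  # R^2 computed directly (summary.lm warns on noiseless round-trip data)
  lnk <- log(rates$k)
  r2 <- 1 - sum(stats::residuals(line)^2) / sum((lnk - mean(lnk))^2)

  structure(
    list(
      rate_constants = rates,
      activation_energy = -slope * gas_constant,
      pre_exponential = exp(intercept),
      gas_constant = gas_constant,
      arrhenius_lm = line,
      r_squared = r2
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("<arrhenius_fit>\n")
  cat(sprintf("  Ea = %.4g kJ mol-1\n", x$activation_energy / 1000))
  cat(sprintf("  A  = %.4g L mol-1 min-1\n", x$pre_exponential))
  cat(sprintf(
    "  Arrhenius line R^2 = %.6f over %d temperatures\n",
    x$r_squared, nrow(x$rate_constants)
  ))
  invisible(x)
}

#' @export
tidy.arrhenius_fit <- function(x, ...) {
  x$rate_constants
}

#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(
    activation_energy = x$activation_energy,
    pre_exponential = x$pre_exponential,
    r.squared = x$r_squared,
    n_temperatures = nrow(x$rate_constants)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
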