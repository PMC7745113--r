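#' Idealised reactor models used as solver cross-checks
#'
#' `pfr_yield()` is the plug-flow limit: every fluid element spends exactly
#' the mean residence time in the reactor, so the yield is the batch
#' conversion at \eqn{\tau}.  `segregated_yield()` is the opposite,
#' zero-radial-mixing limit of fully segregated laminar flow: fluid elements
#' react independently along streamlines and are blended at the outlet with
#' the laminar residence-time distribution
#' \eqn{E(t) = \tau^2 / (2 t^3)} for \eqn{t \ge \tau/2}.
#'
#' Both express the yield as a percentage of the limiting reagent and both
#' bracket the behaviour of the axisymmetric solver: high radial diffusion
#' approaches plug flow, vanishing diffusion approaches full segregation.
#'
#' @inheritParams batch_conversion
#' @param tau Mean residence time, min.
#' @param rel_tol Quadrature relative tolerance.
#' @return Yield as a percentage of the limiting reagent, in `[0, 100]`.
#' @examples
#' pfr_yield(1, 1, 1, 1) # k c0 tau = 1 -> 50%
#' segregated_yield(1, 1, 1, 1)
#' @name reduced-models
NULL

#' @rdname reduced-models
#' @export
pfr_yield <- function(c_a0, c_b0, k, tau) {
  100 * batch_conversion(c_a0, c_b0, k, tau)
}

#' @rdname reduced-models
#' @export
segregated_yield <- function(c_a0, c_b0, k, tau, rel_tol = 1e-8) {
  if (!is.finite(tau) || tau <= 0) abort("tau must be positive")
  if (k == 0) return(0)
  # substitute s = tau / (2 t): E(t) dt = 2 s ds maps the t^-3 RTD tail onto
  # the finite interval s in (0, 1], so no truncation is needed and the
  # integrand stays bounded (X -> its infinite-time limit as s -> 0)
  integrand <- function(s) {
    2 * s * batch_conversion(c_a0, c_b0, k, tau / (2 * s))
  }
  q <- integrate(Vectorize(integrand), lower = 0, upper = 1,
                 rel.tol = rel_tol, subdivisions = 500L)
  if (q$message != "OK") abort(paste0("quadrature failed: ", q$message))
  min(max(100 * q$value, 0), 100)
}

#' Residence-time density of fully developed laminar tube flow
#'
#' \eqn{E(t) = \tau^2/(2 t^3)} for \eqn{t \ge \tau/2}, zero before the
#' first (centerline) element arrives; integrates to 1.
#'
#' @param t Time(s), same units as `tau`.
#' @param tau Mean residence time.
#' @return Density value(s), 1/time.
#' @export
laminar_rtd_density <- function(t, tau) {
  if (!is.finite(tau) || tau <= 0) abort("tau must be positive")
  ifelse(t >= tau / 2, tau^2 / (2 * t^3), 0)
}
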