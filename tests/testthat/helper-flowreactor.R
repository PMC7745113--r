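# shared fixtures: one config load per run, a coarse-but-adequate grid for
# unit tests, and an independent ODE oracle for the integrated rate law

default_cfg <- flow_config()

coarse_grid <- list(n_radial = 16, n_axial = 150)

# brute-force oracle: integrate dcA/dt = -k cA cB numerically and return the
# limiting-reagent conversion at time t (minutes)
ode_conversion <- function(c_a0, c_b0, k, t) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  rhs <- function(time, y, parms) {
    r <- parms$k * y[1] * y[2]
    list(c(-r, -r))
  }
  out <- deSolve::ode(
    y = c(c_a0, c_b0), times = c(0, t), func = rhs, parms = list(k = k),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  c_lim0 <- min(c_a0, c_b0)
  c_lim <- unname(out[nrow(out), 1 + which.min(c(c_a0, c_b0))])
  (c_lim0 - c_lim) / c_lim0
}
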