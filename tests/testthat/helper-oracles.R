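# Independent oracles used across the test suite. Everything here is written
# from first principles (closed forms, or deSolve-based reference integrators
# that do not share code with the package kernels).

# Closed-form solution of the pure-leak membrane: with every conductance but
# g_l at zero, C_m dV/dt = -rho * g_l * (V - E_l), so
# V(t) = E_l + (V0 - E_l) * exp(-rho * g_l * t / C_m).
leak_solution <- function(t, V0, params) {
  rho <- temperature_factors(params$temperature)[["rho"]]
  params$E_l + (V0 - params$E_l) * exp(-rho * params$g_l * t / params$C_m)
}

# Parameter set with only the leak conductance active.
leak_params <- function(...) {
  hb_params(g_d = 0, g_r = 0, g_sd = 0, g_sr = 0, g_h = 0, ...)
}

# Largest Lyapunov exponent of the Lorenz system by the tangent-linear
# (variational) method: hand-written RK4 on the 6-dimensional augmented
# system (state + tangent vector), renormalizing the tangent every step.
# Independent of the package's two-trajectory estimator.
lorenz_tangent_mle <- function(sigma = 10, rho = 28, beta = 8 / 3,
                               total_time = 600, dt = 0.01,
                               transient = 20) {
  f <- function(y) {
    x <- y[1]; yy <- y[2]; z <- y[3]; u <- y[4:6]
    c(sigma * (yy - x),
      x * (rho - z) - yy,
      x * yy - beta * z,
      # tangent vector under the Jacobian of the flow
      -sigma * u[1] + sigma * u[2],
      (rho - z) * u[1] - u[2] - x * u[3],
      yy * u[1] + x * u[2] - beta * u[3])
  }
  step <- function(y) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y <- c(1, 1, 1, 1, 0, 0)
  for (i in seq_len(round(transient / dt))) y <- step(y)
  y[4:6] <- c(1, 0, 0)
  acc <- 0
  steps <- round(total_time / dt)
  for (i in seq_len(steps)) {
    y <- step(y)
    nu <- sqrt(sum(y[4:6]^2))
    acc <- acc + log(nu)
    y[4:6] <- y[4:6] / nu
  }
  acc / (steps * dt)
}

# Fabricate a minimal hb_trajectory for classifier tests without running the
# integrator: a voltage trace plus externally specified spike times.
fake_trajectory <- function(t, V, spike_times, duration = max(t),
                            threshold = -15) {
  structure(
    list(trace = tibble::tibble(t = t, V = V,
                                a_r = 0, a_sd = 0, a_sr = 0, a_h = 0),
         spike_times = spike_times,
         monitor_times = numeric(0), monitor = NA_real_,
         threshold = threshold, dt = NA_real_, duration = duration,
         equilibration = 0, record_stride = 1L, slow_only = FALSE,
         final_state = NULL, params = NULL),
    class = "hb_trajectory"
  )
}
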