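#' Steady-state activation curve
#'
#' Boltzmann activation \eqn{a_\infty(V) = 1/(1 + \exp(-s (V - V_0)))}: the
#' voltage-dependent open probability each gating variable relaxes toward.
#' Increasing in V for positive slope `s` (activation) and decreasing for
#' negative `s` (the h-gate, which opens on hyperpolarization).
#'
#' @param V membrane voltage (mV); vectorized.
#' @param s activation slope (1/mV).
#' @param V0 half-activation voltage (mV).
#' @return Value(s) in (0, 1); exactly 0.5 at `V = V0`.
#' @examples
#' steady_state_activation(-25, s = 0.25, V0 = -25)  # 0.5
#' @export
steady_state_activation <- function(V, s, V0) {
  1 / (1 + exp(-s * (V - V0)))
}

# canonical state vector; a_d is instantaneous and never part of the state
hb_state <- function(V, a_r, a_sd, a_sr, a_h) {
  c(V = V, a_r = a_r, a_sd = a_sd, a_sr = a_sr, a_h = a_h)
}

as_hb_state <- function(state) {
  nm <- c("V", "a_r", "a_sd", "a_sr", "a_h")
  if (!is.numeric(state) || length(state) != 5)
    stop("state must be a numeric vector of length 5 (V, a_r, a_sd, a_sr, a_h)",
         call. = FALSE)
  if (!is.null(names(state))) {
    if (!setequal(names(state), nm)) stop("state names must be ", paste(nm, collapse = ", "), call. = FALSE)
    state <- state[nm]
  } else names(state) <- nm
  state
}

#' Ionic current densities at a given state
#'
#' Evaluates every membrane current of the model at one state. Each current is
#' \eqn{\rho(T)\, g_i\, a_i\, (V - E_i)}; the fast depolarizing gate is
#' instantaneous (\eqn{a_d = a_{d\infty}(V)}), the slow repolarizing current
#' uses the saturable calcium term \eqn{a_{sr}^2/(a_{sr}^2 + K_{sr})}, and the
#' leak gate is identically 1 (but still temperature-scaled by \eqn{\rho}).
#'
#' @param state numeric state vector `(V, a_r, a_sd, a_sr, a_h)`.
#' @param params an [hb_params()] object.
#' @return A one-row tibble with columns `I_d`, `I_r`, `I_sd`, `I_sr`, `I_h`,
#'   `I_l` and their sum `total`, all in uA/cm^2.
#' @export
ionic_currents <- function(state, params) {
  stopifnot(inherits(params, "hb_params"))
  x <- as_hb_state(state)
  tf <- temperature_factors(params$temperature)
  rho <- tf[["rho"]]
  V <- x[["V"]]
  a_d <- steady_state_activation(V, params$s_d, params$V0_d)
  I_d <- rho * params$g_d * a_d * (V - params$E_d)
  I_r <- rho * params$g_r * x[["a_r"]] * (V - params$E_r)
  I_sd <- rho * params$g_sd * x[["a_sd"]] * (V - params$E_sd)
  sr_gate <- x[["a_sr"]]^2 / (x[["a_sr"]]^2 + params$K_sr)
  I_sr <- rho * params$g_sr * sr_gate * (V - params$E_sr)
  I_h <- rho * params$g_h * x[["a_h"]] * (V - params$E_h)
  I_l <- rho * params$g_l * (V - params$E_l)
  tibble::tibble(I_d = I_d, I_r = I_r, I_sd = I_sd, I_sr = I_sr,
                 I_h = I_h, I_l = I_l,
                 total = I_d + I_r + I_sd + I_sr + I_h + I_l)
}

#' Time derivatives of the model state
#'
#' Right-hand side of the HB+Ih ODE system: \eqn{C_m dV/dt = -\sum_i I_i};
#' gating variables relax as \eqn{da_i/dt = \phi(T)(a_{i\infty}(V) - a_i)/\tau_i}
#' for \eqn{i \in \{r, sd, h\}}; the calcium proxy follows
#' \eqn{da_{sr}/dt = \phi(T)(-\eta I_{sd} - \kappa a_{sr})/\tau_{sr}}.
#' With `slow_only = TRUE` the fast spiking pair is removed
#' (\eqn{g_d = g_r = 0}, `a_r` held at 0 with zero derivative), leaving the
#' 4-dimensional slow oscillator.
#'
#' @inheritParams ionic_currents
#' @param slow_only evaluate the 4-variable slow subsystem.
#' @return Named numeric vector of derivatives (same layout as `state`).
#' @export
hb_derivatives <- function(state, params, slow_only = FALSE) {
  x <- as_hb_state(state)
  if (any(!is.finite(x)))
    stop("non-finite state: integration blow-up", call. = FALSE)
  if (slow_only) x[["a_r"]] <- 0
  out <- cpp_deriv(unname(x), param_vector(params), slow_only)
  names(out) <- names(x)
  out
}

#' Numerical Jacobian of the vector field
#'
#' Central finite differences with a relative step of about 1e-6 per variable.
#' For the slow subsystem the `a_r` row and column are dropped, giving a 4 x 4
#' matrix; otherwise 5 x 5.
#'
#' @inheritParams hb_derivatives
#' @return Square matrix with dimnames from the state variables.
#' @export
numeric_jacobian <- function(state, params, slow_only = FALSE) {
  x <- as_hb_state(state)
  vars <- if (slow_only) c("V", "a_sd", "a_sr", "a_h") else names(x)
  n <- length(vars)
  J <- matrix(0, n, n, dimnames = list(vars, vars))
  for (j in seq_len(n)) {
    v <- vars[j]
    h <- 1e-6 * max(abs(x[[v]]), 1)
    xp <- x; xp[[v]] <- x[[v]] + h
    xm <- x; xm[[v]] <- x[[v]] - h
    fp <- hb_derivatives(xp, params, slow_only)
    fm <- hb_derivatives(xm, params, slow_only)
    J[, j] <- (fp[vars] - fm[vars]) / (2 * h)
  }
  J
}
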