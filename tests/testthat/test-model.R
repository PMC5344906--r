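test_that("steady-state activation is a Boltzmann curve", {
  expect_equal(steady_state_activation(-25, s = 0.25, V0 = -25), 0.5)
  expect_equal(steady_state_activation(-40, s = 0.11, V0 = -40), 0.5)
  # positive slope: increasing in V; negative slope (h gate): decreasing
  v <- seq(-100, 20, by = 1)
  expect_true(all(diff(steady_state_activation(v, 0.25, -25)) > 0))
  expect_true(all(diff(steady_state_activation(v, -0.14, -85)) < 0))
  expect_true(all(steady_state_activation(v, 0.11, -40) > 0))
  expect_true(all(steady_state_activation(v, 0.11, -40) < 1))
  # closed-form spot check
  expect_equal(steady_state_activation(-60, 0.11, -40),
               1 / (1 + exp(-0.11 * (-60 + 40))), tolerance = 1e-15)
})

test_that("ionic currents match a hand computation at the reference temperature", {
  # At T = 25 both temperature factors are 1, so every current is its
  # unscaled form g * gate * (V - E).
  p <- hb_params(temperature = 25)
  st <- c(V = -60, a_r = 0.1, a_sd = 0.2, a_sr = 0.3, a_h = 0.4)
  cur <- ionic_currents(st, p)
  a_d <- 1 / (1 + exp(-0.25 * (-60 + 25)))
  expect_equal(cur$I_d, 2.5 * a_d * (-60 - 50), tolerance = 1e-12)
  expect_equal(cur$I_r, 2.8 * 0.1 * (-60 + 90), tolerance = 1e-12)
  expect_equal(cur$I_sd, 0.21 * 0.2 * (-60 - 50), tolerance = 1e-12)
  expect_equal(cur$I_sr, 0.28 * (0.3^2 / (0.3^2 + 0.16)) * (-60 + 90),
               tolerance = 1e-12)
  expect_equal(cur$I_h, 0.4 * 0.4 * (-60 + 30), tolerance = 1e-12)
  expect_equal(cur$I_l, 0.06 * (-60 + 80), tolerance = 1e-12)
  expect_equal(cur$total,
               cur$I_d + cur$I_r + cur$I_sd + cur$I_sr + cur$I_h + cur$I_l)
})

test_that("the sr gate saturates in a_sr with half-activation at sqrt(K_sr)", {
  p <- hb_params(temperature = 25)
  st <- function(a) c(V = -60, a_r = 0, a_sd = 0, a_sr = a, a_h = 0)
  # half of the asymptotic conductance at a_sr = sqrt(K_sr) = 0.4
  i_half <- ionic_currents(st(0.4), p)$I_sr
  expect_equal(i_half, 0.5 * 0.28 * (-60 + 90), tolerance = 1e-12)
  # saturation: gate -> 1 as a_sr grows
  i_big <- ionic_currents(st(50), p)$I_sr
  expect_equal(i_big, 0.28 * (-60 + 90), tolerance = 1e-3)
  # with the legacy constant read as 0.42 the same state gives the documented
  # 2.485 uA/cm^2
  p42 <- hb_params(temperature = 25, K_sr = 0.42)
  expect_equal(ionic_currents(st(0.42), p42)$I_sr,
               0.28 * (0.42^2 / (0.42^2 + 0.42)) * 30, tolerance = 1e-12)
  expect_equal(ionic_currents(st(0.42), p42)$I_sr, 2.485, tolerance = 1e-3)
})

test_that("currents scale with rho(T) only", {
  st <- c(V = -60, a_r = 0.1, a_sd = 0.2, a_sr = 0.3, a_h = 0.4)
  c25 <- ionic_currents(st, hb_params(temperature = 25))
  c36 <- ionic_currents(st, hb_params(temperature = 36))
  rho <- temperature_factors(36)[["rho"]]
  for (nm in c("I_d", "I_r", "I_sd", "I_sr", "I_h", "I_l"))
    expect_equal(c36[[nm]], rho * c25[[nm]], tolerance = 1e-12)
})

test_that("derivatives implement the stated kinetics", {
  p <- hb_params(temperature = 36)
  tf <- temperature_factors(36)
  st <- c(V = -60, a_r = 0.1, a_sd = 0.2, a_sr = 0.3, a_h = 0.4)
  d <- hb_derivatives(st, p)
  # dV/dt = -total / C_m
  expect_equal(d[["V"]], -ionic_currents(st, p)$total / p$C_m,
               tolerance = 1e-10)
  # relaxation kinetics, scaled by phi
  expect_equal(d[["a_r"]],
               tf[["phi"]] * (steady_state_activation(-60, 0.25, -25) - 0.1) / 2,
               tolerance = 1e-12)
  expect_equal(d[["a_h"]],
               tf[["phi"]] * (steady_state_activation(-60, -0.14, -85) - 0.4) / 125,
               tolerance = 1e-12)
  # calcium proxy: phi * (-eta * I_sd - kappa * a_sr) / tau_sr
  I_sd <- ionic_currents(st, p)$I_sd
  expect_equal(d[["a_sr"]],
               tf[["phi"]] * (-0.014 * I_sd - 0.18 * 0.3) / 35,
               tolerance = 1e-12)
})

test_that("a_sr growth is non-negative at a_sr = 0 below E_sd", {
  p <- hb_params()
  for (v in c(-80, -60, -20, 0, 49)) {
    st <- c(V = v, a_r = 0.1, a_sd = 0.5, a_sr = 0, a_h = 0.1)
    expect_gte(hb_derivatives(st, p)[["a_sr"]], 0)
  }
})

test_that("slow subsystem removes the fast pair", {
  p <- hb_params()
  st <- c(V = -60, a_r = 0.3, a_sd = 0.2, a_sr = 0.3, a_h = 0.4)
  d <- hb_derivatives(st, p, slow_only = TRUE)
  expect_identical(d[["a_r"]], 0)
  # voltage derivative excludes I_d and I_r
  p0 <- hb_params(g_d = 0, g_r = 0)
  st0 <- st; st0[["a_r"]] <- 0
  cur <- ionic_currents(st0, p0)
  expect_equal(d[["V"]], -cur$total / p$C_m, tolerance = 1e-10)
})

test_that("non-finite states are refused", {
  expect_error(hb_derivatives(c(V = Inf, a_r = 0, a_sd = 0, a_sr = 0, a_h = 0),
                              hb_params()), "non-finite")
  expect_error(hb_derivatives(c(1, 2, 3), hb_params()), "length 5")
  expect_error(hb_derivatives(c(a = 1, b = 2, c = 3, d = 4, e = 5), hb_params()),
               "names")
})

test_that("numerical Jacobian matches analytic entries", {
  p <- hb_params(temperature = 36)
  phi <- temperature_factors(36)[["phi"]]
  st <- c(V = -60, a_r = 0.1, a_sd = 0.2, a_sr = 0.3, a_h = 0.4)
  J <- numeric_jacobian(st, p)
  expect_identical(dim(J), c(5L, 5L))
  # each gate's self-relaxation: d(da_i/dt)/da_i = -phi / tau_i
  expect_equal(J["a_r", "a_r"], -phi / 2, tolerance = 1e-6)
  expect_equal(J["a_sd", "a_sd"], -phi / 10, tolerance = 1e-6)
  expect_equal(J["a_h", "a_h"], -phi / 125, tolerance = 1e-6)
  expect_equal(J["a_sr", "a_sr"], -phi * 0.18 / 35, tolerance = 1e-6)
  # gates do not couple to each other directly
  expect_equal(J["a_r", "a_h"], 0, tolerance = 1e-8)
  expect_equal(J["a_h", "a_sd"], 0, tolerance = 1e-8)
  # dV/dt depends on a_r with coefficient -rho g_r (V - E_r) / C_m
  rho <- temperature_factors(36)[["rho"]]
  expect_equal(J["V", "a_r"], -rho * 2.8 * (-60 + 90), tolerance = 1e-5)
  # slow subsystem drops the a_r row/column
  J4 <- numeric_jacobian(st, p, slow_only = TRUE)
  expect_identical(dimnames(J4)[[1]], c("V", "a_sd", "a_sr", "a_h"))
})

test_that("default initial state sits on every gating nullcline", {
  for (slow in c(FALSE, TRUE)) {
    p <- hb_params(temperature = 36)
    st <- default_initial_state(p, slow_only = slow)
    expect_identical(st[["V"]], -60)
    expect_gte(st[["a_sr"]], 0)
    d <- hb_derivatives(st, p, slow_only = slow)
    for (nm in c("a_r", "a_sd", "a_sr", "a_h"))
      expect_equal(d[[nm]], 0, tolerance = 1e-12)
  }
  expect_identical(default_initial_state(hb_params(), TRUE)[["a_r"]], 0)
})
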