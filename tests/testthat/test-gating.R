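test_that("direct gating: steady state, limits and rhs fixed point", {
  g <- direct_gating(k = 2)
  expect_identical(open_fraction_ss(0, g), 1)
  expect_identical(open_fraction_ss(0.5, g), 0.5)
  expect_equal(open_fraction_ss(1e12, g), 0, tolerance = 1e-11)
  # rhs vanishes exactly at the steady state, is +1 at a fully closed gate
  for (u in c(0, 0.3, 2, 50)) {
    expect_equal(gate_rhs(open_fraction_ss(u, g), u, g), 0, tolerance = 1e-14)
  }
  expect_identical(gate_rhs(1, 0, g), 0)
  expect_identical(gate_rhs(0, 7, g), 1)
})

test_that("indirect gating: steady state, sensor floor and rhs", {
  g <- indirect_gating(kC = 1, cac0 = 10)
  expect_identical(open_fraction_ss(0, g), 1)
  expect_equal(open_fraction_ss(1, g), 2 / 12)
  # the floor 1/(cac0+1) is approached from above, never crossed
  u <- 10^seq(-3, 8, by = 0.25)
  v <- open_fraction_ss(u, g)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 1 / 11))
  expect_equal(open_fraction_ss(1e9, g), 1 / 11, tolerance = 1e-8)
  g2 <- indirect_gating(kC = 1, cac0 = 20)
  expect_equal(gate_rhs(1, 1, g2), -10)
  for (u in c(0, 0.5, 3)) {
    expect_equal(gate_rhs(open_fraction_ss(u, g2), u, g2), 0, tolerance = 1e-14)
  }
})

test_that("direct and indirect open fractions coincide at zero calcium", {
  for (cac0 in c(5, 10, 50, 100)) {
    expect_identical(open_fraction_ss(0, indirect_gating(1, cac0)),
                     open_fraction_ss(0, direct_gating(2)))
  }
})

test_that("gate time constant matches its closed form and limits", {
  g <- indirect_gating(kC = 1, cac0 = 20)
  expect_identical(gate_time_constant(0, g), 1)
  expect_equal(gate_time_constant(1, g), 2 / 22)
  # large-sensor, high-calcium limit ~ 1/cac0
  g2 <- indirect_gating(kC = 1, cac0 = 500)
  expect_equal(gate_time_constant(1e6, g2), 1 / 500, tolerance = 1e-2)
})

test_that("analytic gate solution matches stiff ODE integration", {
  g <- indirect_gating(kC = 1, cac0 = 20)
  eta <- seq(0, 2, length.out = 201)
  for (u0 in c(0.01, 0.5, 5)) {
    for (u1 in c(0.1, 1, 20)) {
      ode <- deSolve::lsoda(c(c = open_fraction_ss(u0, g)), eta,
                            function(t, st, p) list(gate_rhs(st[1], u1, g)),
                            parms = NULL, rtol = 1e-11, atol = 1e-13)
      expect_lt(max(abs(ode[, 2] - gate_analytic(eta, u0, u1, g))), 1e-8)
    }
  }
})

test_that("pump flux is saturating Michaelis and the kinetic mode agrees at steady state", {
  pp <- pump_params(kA = 1)
  expect_identical(pump_flux(0, pp), 0)
  expect_identical(pump_flux(1, pp), 0.5)
  expect_equal(pump_flux(1e9, pp), 1, tolerance = 1e-8)
  # kinetic mode: steady bound fraction ka*u/(ka*u + kb) = u/(kA + u) for kA = kb/ka
  pk <- pump_params(kA = 2, ka = 3, kb = 6)
  for (u in c(0.1, 2, 10)) {
    w_ss <- pk$ka * u / (pk$ka * u + pk$kb)
    expect_equal(pump_kinetic_rhs(w_ss, u, pk), 0, tolerance = 1e-14)
    expect_equal(w_ss, pump_flux(u, pk), tolerance = 1e-14)
  }
})

test_that("cilium-to-body current vanishes at the Nernst balance and with zero conductance", {
  cb <- cilium_body_params(nu_t = 0.5, psi_tr = 0, ut = 0.025)
  expect_equal(cilium_body_current(0.025, -1, cb), 0, tolerance = 1e-15)
  cb2 <- cilium_body_params(nu_t = 0.5, psi_tr = 0.5 * log(4), ut = 1)
  expect_equal(cilium_body_current(4, 0.3, cb2), 0, tolerance = 1e-15)
  off <- cilium_body_params(nu_t = 0, psi_tr = 2, ut = 0.025)
  expect_identical(cilium_body_current(5, -1, off), 0)
  expect_error(cilium_body_current(0, -1, cb), "positive")
})

test_that("gate fixed points are attracting (negative slope in the gate variable)", {
  for (g in list(direct_gating(2), indirect_gating(1, 20),
                 indirect_gating(0.3, 100))) {
    for (u in c(0, 0.1, 1, 30)) {
      slope <- (gate_rhs(0.6 + 1e-6, u, g) - gate_rhs(0.6 - 1e-6, u, g)) / 2e-6
      expect_lt(slope, 0)
    }
  }
})
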