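test_that("variant reductions are exact on a state grid", {
  p <- tab_coupled(vCah = 0, vKca = 0, vCat = 0)
  u <- rep(10^seq(-2, 1, length.out = 7), each = 5)
  psi <- rep(seq(-2, 1, length.out = 5), times = 7)
  base <- coupled_rhs(u, psi, p, I0 = 0.3, variant = "base")
  hyper <- coupled_rhs(u, psi, p, I0 = 0.3, variant = "hyper")
  full <- coupled_rhs(u, psi, p, I0 = 0.3, variant = "full")
  expect_identical(base$du, hyper$du)
  expect_identical(base$dpsi, hyper$dpsi)
  expect_identical(hyper$du, full$du)
  expect_identical(hyper$dpsi, full$dpsi)
  # with the optional scales on, the variants genuinely differ
  p2 <- tab_coupled(vCah = 0.9, vKca = 0.2, vCat = 0.1)
  h2 <- coupled_rhs(u, psi, p2, I0 = 0.3, variant = "hyper")
  f2 <- coupled_rhs(u, psi, p2, I0 = 0.3, variant = "full")
  expect_gt(max(abs(h2$dpsi - base$dpsi)), 1e-3)
  expect_gt(max(abs(f2$du - h2$du)), 1e-6)
})

test_that("the rest state is a fixed point and a flat trajectory stays on it", {
  p <- tab_coupled()
  r <- rest_state(p, I0 = 0)
  expect_lt(r$residual, 1e-10)
  tr <- simulate_free(p, schedule = 0, duration = 100)
  expect_lt(max(abs(tr$u - r$u)), 1e-6)
  expect_lt(max(abs(tr$psi - r$psi)), 1e-6)
})

test_that("with conductances and I0 off, calcium decays under the pump at constant potential", {
  p <- coupled_params(b = 0, b1 = 0, nuCast = 0, nuKst = 0)
  tr <- simulate_free(p, schedule = 0, init = c(2, -1), duration = 20)
  expect_true(all(diff(tr$u) < 0))
  expect_lt(max(abs(tr$psi - (-1))), 1e-9)
})

test_that("increasing inward current depolarises the resting state", {
  p <- tab_coupled()
  r0 <- rest_state(p, I0 = 0)
  r1 <- rest_state(p, I0 = 0.2)
  expect_gt(r1$psi, r0$psi)
})

test_that("a small current step elicits one paired pulse of calcium and potential", {
  p <- tab_coupled()
  tr <- simulate_free(p, schedule = current_schedule(c(0, 20), c(0, 0.2)),
                      duration = 300)
  m <- spike_metrics(tr)
  expect_identical(m$n_extrema, 1L)
  expect_gt(m$peak, 3 * m$baseline)          # a genuine calcium pulse
  expect_lt(m$final_ss, 1.5 * m$baseline)    # returns near rest
  ipk_u <- which.max(tr$u)
  ipk_psi <- which.max(tr$psi)
  expect_gt(tr$psi[ipk_psi], tr$psi[1] + 0.5)  # potential pulses too
  expect_lt(abs(tr$eta[ipk_psi] - tr$eta[ipk_u]), 10)  # paired in time
})

test_that("an intermediate current sustains oscillations of both variables", {
  p <- tab_coupled()
  tr <- simulate_free(p, schedule = 0.45, duration = 400)
  tail <- tr[tr$eta > 200, ]
  expect_gt(max(tail$u) - min(tail$u), 0.5)
  expect_gt(max(tail$psi) - min(tail$psi), 0.3)
})

test_that("free-membrane spike dynamics differ measurably from clamp dynamics", {
  p <- tab_coupled()
  free <- simulate_free(p, schedule = current_schedule(c(0, 20), c(0, 0.2)),
                        duration = 300)
  clamp <- simulate_clamp(clamp_protocol(psi1 = 0.5, mechanism = "indirect"),
                          tab_clamp_indirect())
  tfree <- free$eta[which.max(free$u)] - 20
  tclamp <- clamp$eta[which.max(clamp$u)]
  expect_gt(abs(tfree - tclamp), 1)
})

test_that("current schedules are validated and applied at the right times", {
  expect_error(current_schedule(c(1, 2), c(0, 1)), "eta = 0")
  expect_error(current_schedule(c(0, 0), c(0, 1)), "increasing")
  sch <- current_schedule(c(0, 50), c(0, 1))
  p <- tab_coupled()
  tr <- simulate_free(p, schedule = sch, duration = 80)
  before <- tr[tr$eta < 49, ]
  expect_lt(max(abs(before$u - before$u[1])), 1e-5)  # nothing before the step
  expect_gt(max(tr$u) , before$u[1] * 1.5)           # response after it
})

test_that("current-voltage characteristic: transient amplitudes grow steeply, stationary current is monotone", {
  pa <- clamp_params("direct", b = 2, b1 = 1)
  # a zero-size step has zero transient amplitude by construction
  iv0 <- iv_characteristic(pa, -1.2, psi0 = -1.2)
  expect_equal(abs(iv0$peak_i_ca), 0, tolerance = 1e-6)
  expect_equal(abs(iv0$peak_i_full), 0, tolerance = 1e-6)
  grid <- seq(-1, 0.5, by = 0.25)
  iv <- iv_characteristic(pa, grid, psi0 = -1.2)
  amp <- abs(iv$peak_i_full)
  expect_true(all(diff(amp[seq_len(which.max(amp))]) > 0))
  # near-exponential growth below conductance saturation
  rising <- seq_len(which.max(amp) - 1L)
  expect_gte(length(rising), 4)
  fit <- stats::lm(log(amp[rising]) ~ grid[rising])
  expect_gt(summary(fit)$r.squared, 0.9)
  # the stationary full current is potassium-dominated: monotone in psi
  expect_true(all(diff(iv$stationary_i_full) < 0))
})
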