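test_that("the clamp rest state is a true fixed point of the dynamics", {
  for (pa in list(tab_clamp_direct(), tab_clamp_indirect())) {
    st <- clamp_initial_state(pa, -1.2)
    expect_lt(st$residual, 1e-10)
    expect_equal(st$gate, open_fraction_ss(st$u, pa$gating), tolerance = 1e-12)
    pr <- clamp_protocol(psi0 = -1.2, psi1 = -1.2, duration = 20,
                         mechanism = pa$mechanism)
    rhs0 <- oracle_clamp_rhs(5, st$u, st$gate, pa, pr)
    expect_lt(max(abs(rhs0)), 1e-10)
  }
})

test_that("a null step leaves the system at rest for the whole run", {
  pa <- tab_clamp_direct()
  pr <- clamp_protocol(psi0 = -1.2, psi1 = -1.2, duration = 30,
                       mechanism = "direct")
  tr <- simulate_clamp(pr, pa)
  st <- clamp_initial_state(pa, -1.2)
  expect_lt(max(abs(tr$u - st$u)), 1e-7)
  expect_lt(max(abs(tr$gate - st$gate)), 1e-8)
  expect_equal(spike_metrics(tr)$amplitude, 0, tolerance = 1e-7)
})

test_that("stored currents are recomputable from the stored state", {
  pa <- tab_clamp_direct()
  pr <- clamp_protocol(psi0 = -1.2, psi1 = 0.5, duration = 40,
                       mechanism = "direct", include_K = TRUE)
  tr <- simulate_clamp(pr, pa)
  cur <- clamp_currents(tr$eta, tr$u, tr$gate, pa, pr)
  expect_lt(max(abs(cur$i_ca - tr$i_ca)), 1e-9)
  expect_lt(max(abs(cur$i_k - tr$i_k)), 1e-9)
  expect_lt(max(abs(cur$i_full - tr$i_full)), 1e-9)
  # independent formulation of the calcium balance agrees with du/deta
  mid <- seq(100, 1900, by = 200)
  du_num <- (tr$u[mid + 1] - tr$u[mid - 1]) / (tr$eta[mid + 1] - tr$eta[mid - 1])
  du_mod <- vapply(mid, function(i)
    oracle_clamp_rhs(tr$eta[i], tr$u[i], tr$gate[i], pa, pr)[1], numeric(1))
  expect_lt(max(abs(du_num - du_mod)), 1e-2 * max(abs(du_mod)) + 1e-6)
})

test_that("positivity and state bounds hold along clamp trajectories", {
  for (psi1 in c(-1, 0, 0.5)) {
    tr <- simulate_clamp(clamp_protocol(psi1 = psi1, mechanism = "indirect"),
                         tab_clamp_indirect())
    expect_true(all(tr$u > 0))
    expect_true(all(tr$gate >= 0 & tr$gate <= 1))
  }
})

test_that("the depolarising step produces a biphasic inward current", {
  tr <- simulate_clamp(clamp_protocol(psi0 = -1.2, psi1 = 0.5,
                                      mechanism = "direct"),
                       tab_clamp_direct())
  ic <- tr$i_ca
  # under the signed convention the inward transient is positive: a fast
  # rising phase (conductance relaxation) then decay back to balance
  ipk <- which.max(abs(ic))
  expect_lt(tr$eta[ipk], 1)
  expect_gt(abs(ic[ipk]), abs(ic[1]) + 0.5)            # fast inward phase
  expect_lt(abs(ic[length(ic)]), abs(ic[ipk]) - 0.5)   # relaxation phase
  expect_equal(ic[length(ic)], 0, tolerance = 1e-2)    # balance at new rest
})

test_that("the steady-state calcium curve is bell-shaped over the depolarisation range", {
  pa <- tab_clamp_direct()
  grid <- seq(-1.2, 1.5, by = 0.05)
  cur <- steady_state_u(pa, grid)
  expect_true(all(is.finite(cur$u)))
  expect_true(all(cur$residual < 1e-8))
  imax <- which.max(cur$u)
  expect_gt(imax, 5)                  # rises first
  expect_lt(imax, length(grid) - 3)   # then falls
  expect_true(all(diff(cur$u[1:imax]) > 0))
  expect_true(all(diff(cur$u[imax:length(grid)]) < 0))
})

test_that("direct and indirect steady curves coincide at the low-calcium end", {
  dir <- steady_state_u(tab_clamp_direct(), c(-2.5, -2.2, -2))
  ind <- steady_state_u(tab_clamp_indirect(), c(-2.5, -2.2, -2))
  # both gates approach 1 as u -> 0, so the balances agree
  expect_equal(dir$u, ind$u, tolerance = 0.02)
})

test_that("disabling the sensor (cac0 = 0) keeps the gate fully open", {
  pa <- tab_clamp_indirect(cac0 = 0)
  tr <- simulate_clamp(clamp_protocol(psi1 = 0.2, mechanism = "indirect"), pa)
  expect_true(all(abs(tr$gate - 1) < 1e-6))
})

test_that("spike metrics are deterministic and refine consistently", {
  pr <- clamp_protocol(psi1 = 0.5, mechanism = "indirect")
  pa <- tab_clamp_indirect()
  m1 <- spike_metrics(simulate_clamp(pr, pa, n_out = 2001))
  m2 <- spike_metrics(simulate_clamp(pr, pa, n_out = 6001))
  expect_equal(m1$peak, m2$peak, tolerance = 1e-5)
  expect_equal(m1$final_ss, m2$final_ss, tolerance = 1e-7)
  expect_identical(m1$n_extrema, m2$n_extrema)
  # flat trajectory: zero amplitude, no extrema
  flat <- data.frame(eta = 0:100, u = rep(1, 101))
  expect_identical(spike_metrics(flat)$n_extrema, 0L)
  expect_identical(spike_metrics(flat)$amplitude, 0)
  # single synthetic pulse
  eta <- seq(0, 10, by = 0.01)
  pulse <- data.frame(eta = eta, u = 1 + 3 * eta * exp(-eta))
  expect_identical(spike_metrics(pulse)$n_extrema, 1L)
})

test_that("spike amplitude grows with external calcium", {
  sc <- scan_spike_amplitude(tab_clamp_indirect(),
                             clamp_protocol(psi1 = 0.5, mechanism = "indirect"),
                             vary = "uout", grid = c(100, 300, 1000, 3000))
  expect_true(all(is.na(sc$error)))
  expect_true(all(diff(sc$peak) > 0))
  expect_true(all(diff(sc$peak_current) > 0))
})

test_that("mismatched mechanism between protocol and params is rejected", {
  expect_error(simulate_clamp(clamp_protocol(mechanism = "indirect"),
                              tab_clamp_direct()),
               "mechanism")
  expect_error(clamp_params("direct", gating = indirect_gating()), "direct")
  expect_error(clamp_protocol(tau0 = -1), "tau0")
  expect_error(clamp_protocol(duration = 0), "duration")
})
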