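test_that("nullcline samples lie on their defining zero sets", {
  p <- tab_coupled()
  nc <- compute_nullclines(p, "base", I0 = 0, n_u = 80, n_psi = 300)
  if (nrow(nc$u_nullcline)) {
    res <- abs(coupled_rhs(nc$u_nullcline$u, nc$u_nullcline$psi, p, 0, "base")$du)
    expect_lt(max(res), 1e-8)
  }
  res2 <- abs(coupled_rhs(nc$psi_nullcline$u, nc$psi_nullcline$psi, p, 0, "base")$dpsi)
  expect_lt(max(res2), 1e-8)
})

test_that("the potential nullcline is N-shaped and the calcium nullcline monotone", {
  p <- tab_coupled()
  nc <- compute_nullclines(p, "base", I0 = 0, n_u = 160, n_psi = 500)
  expect_gte(nrow(nc$turning_points), 2)
  expect_gte(max(nc$psi_counts), 3)
  low <- stats::aggregate(psi ~ u, data = nc$u_nullcline, FUN = min)
  low <- low[order(low$u), ]
  expect_gt(nrow(low), 20)
  expect_true(all(diff(low$psi) > 0))
})

test_that("fixed points satisfy the dynamics to tight residual and match stability labels", {
  p <- tab_coupled()
  wide <- list(u = c(0.005, 80), psi = c(-3, 4))
  for (I0 in c(0, 0.5, 1)) {
    fps <- find_fixed_points(p, "base", I0, wide, grid_n = 150)
    expect_gte(nrow(fps), 1)
    expect_true(all(fps$residual < 1e-10))
    for (i in seq_len(nrow(fps))) {
      # perturb and integrate: stable points attract, unstable repel
      init <- c(fps$u[i] * 1.02, fps$psi[i] + 0.01)
      tr <- simulate_free(p, schedule = I0, init = init, duration = 150)
      d_end <- abs(tr$u[nrow(tr)] - fps$u[i]) / fps$u[i]
      if (grepl("^stable", fps$stability[i])) {
        expect_lt(d_end, 0.02)
      } else {
        # departs well beyond the 2% seed perturbation
        expect_gt(max(abs(tr$u - fps$u[i])) / fps$u[i], 0.06)
        expect_gt(max(abs(tr$psi - fps$psi[i])), 0.1)
      }
    }
  }
})

test_that("saddles are only reported with a negative Jacobian determinant", {
  p <- tab_coupled()
  fps <- find_fixed_points(p, "base", 0.5,
                           list(u = c(0.005, 80), psi = c(-3, 4)))
  for (i in seq_len(nrow(fps))) {
    J <- coupled_jacobian(fps$u[i], fps$psi[i], p, 0.5, "base")
    if (det(J) > 0) expect_true(fps$stability[i] != "saddle")
    else expect_identical(fps$stability[i], "saddle")
  }
})

test_that("root finding agrees with a brute-force sign-change grid scan", {
  p <- tab_coupled()
  window <- list(u = c(0.05, 40), psi = c(-2.5, 2))
  for (I0 in c(0, 0.5)) {
    fps <- find_fixed_points(p, "base", I0, window, grid_n = 150)
    ug <- exp(seq(log(window$u[1]), log(window$u[2]), length.out = 400))
    pg <- seq(window$psi[1], window$psi[2], length.out = 400)
    r <- coupled_rhs(rep(ug, length(pg)), rep(pg, each = length(ug)), p, I0, "base")
    F1 <- matrix(r$du, length(ug)); F2 <- matrix(r$dpsi, length(ug))
    cell <- function(M) {
      s <- sign(M)
      (s[-nrow(s), -ncol(s)] != s[-1, -ncol(s)]) |
        (s[-nrow(s), -ncol(s)] != s[-nrow(s), -1]) |
        (s[-nrow(s), -ncol(s)] != s[-1, -1])
    }
    hits <- which(cell(F1) & cell(F2), arr.ind = TRUE)
    # every root sits inside (or adjacent to) a flagged cell
    for (i in seq_len(nrow(fps))) {
      iu <- findInterval(fps$u[i], ug); ip <- findInterval(fps$psi[i], pg)
      expect_true(any(abs(hits[, 1] - iu) <= 1 & abs(hits[, 2] - ip) <= 1))
    }
    # every cluster of flagged cells contains a root
    if (nrow(hits)) {
      near_root <- vapply(seq_len(nrow(hits)), function(k) {
        any(abs(fps$u - sqrt(ug[hits[k, 1]] * ug[hits[k, 1] + 1])) <
              (ug[hits[k, 1] + 1] - ug[hits[k, 1]]) * 3 &
            abs(fps$psi - pg[hits[k, 2]]) < (pg[2] - pg[1]) * 3)
      }, logical(1))
      expect_true(all(near_root))
    }
  }
})

test_that("limit-cycle detection finds the oscillation and rejects the rest state", {
  p <- tab_coupled()
  expect_null(detect_limit_cycle(p, "base", I0 = 0.1, horizon = 300))
  cyc <- detect_limit_cycle(p, "base", I0 = 0.5, horizon = 600)
  expect_false(is.null(cyc))
  expect_gt(cyc$period, 0)
  expect_gt(cyc$u_amplitude, 0)
  expect_gt(cyc$psi_amplitude, 0)
  expect_lt(cyc$period_spread, 0.01)
})

test_that("regime classification is stable under tighter integrator tolerances", {
  p <- tab_coupled()
  a <- classify_regime(p, "base", 0.2)
  b <- classify_regime(p, "base", 0.2, horizon = 500)
  expect_identical(a$mode, "single_spike")
  expect_identical(a$mode, b$mode)
  osc <- classify_regime(p, "base", 0.5)
  expect_identical(osc$mode, "oscillation")
  expect_false(is.null(osc$limit_cycle))
  sw <- classify_regime(p, "base", 1)
  expect_identical(sw$mode, "switch")
})
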