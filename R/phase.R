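#' Nullclines of the coupled system
#'
#' Traces the two nullclines of the (u, psi) phase plane by per-grid-line
#' root finding: for every calcium value on a log-spaced grid the potentials
#' with `du/deta = 0` (u-nullcline) and `dpsi/deta = 0` (psi-nullcline) are
#' bracketed on a fine potential grid and polished with `uniroot`. Grid
#' lines without a zero crossing are recorded as gaps, not interpolated.
#'
#' The default window covers the physiological ranges `u` in \[0.01, 10\]
#' (0.04--40 uM on the calmodulin scale) and `psi` in \[-2, 1\].
#'
#' @param params A [coupled_params()] object.
#' @param variant Model variant.
#' @param I0 Inward current.
#' @param window List with `u = c(min, max)` and `psi = c(min, max)`.
#' @param n_u Number of calcium grid lines.
#' @param n_psi Resolution of the potential bracketing grid.
#' @return An object of class `ciliary_nullclines`: list with data.frames
#'   `u_nullcline` and `psi_nullcline` (columns `u`, `psi`, `root_id`), the
#'   per-line root counts, and the detected turning points of the
#'   psi-nullcline.
#' @export
compute_nullclines <- function(params, variant = "base", I0 = 0,
                               window = list(u = c(0.01, 10), psi = c(-2, 1)),
                               n_u = 240, n_psi = 600) {
  stopifnot(inherits(params, "coupled_params"))
  ugrid <- exp(seq(log(window$u[1]), log(window$u[2]), length.out = n_u))
  psigrid <- seq(window$psi[1], window$psi[2], length.out = n_psi)

  trace_one <- function(component) {
    val <- function(u, psi) {
      r <- coupled_rhs(rep(u, length(psi)), psi, params, I0, variant)
      r[[component]]
    }
    pts <- list(); counts <- integer(n_u)
    for (i in seq_along(ugrid)) {
      v <- val(ugrid[i], psigrid)
      sc <- which(v[-1] * v[-length(v)] < 0)
      roots <- vapply(sc, function(j)
        stats::uniroot(function(ps) val(ugrid[i], ps)[1],
                       c(psigrid[j], psigrid[j + 1]), tol = 1e-12)$root,
        numeric(1))
      exact <- psigrid[v == 0]
      roots <- sort(c(roots, exact))
      counts[i] <- length(roots)
      if (length(roots))
        pts[[length(pts) + 1L]] <- data.frame(u = ugrid[i], psi = roots,
                                              root_id = seq_along(roots))
    }
    list(points = if (length(pts)) do.call(rbind, pts)
                  else data.frame(u = numeric(0), psi = numeric(0),
                                  root_id = integer(0)),
         counts = counts)
  }

  un <- trace_one("du")
  pn <- trace_one("dpsi")

  ## turning points (folds) of the psi-nullcline: grid intervals where the
  ## root count jumps by 2 (a pair of roots is born or annihilated)
  dcount <- diff(pn$counts)
  fold_idx <- which(abs(dcount) == 2)
  turning <- if (length(fold_idx)) {
    data.frame(u = sqrt(ugrid[fold_idx] * ugrid[fold_idx + 1L]),
               direction = ifelse(dcount[fold_idx] > 0, "birth", "merge"))
  } else {
    data.frame(u = numeric(0), direction = character(0))
  }

  structure(list(u_nullcline = un$points, psi_nullcline = pn$points,
                 u_counts = un$counts, psi_counts = pn$counts,
                 turning_points = turning, u_grid = ugrid,
                 window = window, I0 = I0, variant = variant),
            class = "ciliary_nullclines")
}

#' @export
print.ciliary_nullclines <- function(x, ...) {
  cat(sprintf(paste0("ciliary_nullclines (%s, I0 = %g): %d u-nullcline and ",
                     "%d psi-nullcline samples, %d psi-nullcline turning point(s)\n"),
              x$variant, x$I0, nrow(x$u_nullcline), nrow(x$psi_nullcline),
              nrow(x$turning_points)))
  invisible(x)
}

#' Fixed points of the coupled system with linear stability
#'
#' Scans a (log-u, psi) grid for cells where both components of the
#' right-hand side change sign, polishes each candidate with damped Newton
#' iteration, deduplicates, and classifies each root by the eigenvalues of
#' the numerical Jacobian (`stable_node`, `stable_focus`, `unstable_focus`,
#' `unstable_node`, `saddle`).
#'
#' @param params A [coupled_params()] object.
#' @param variant Model variant.
#' @param I0 Inward current.
#' @param window List with `u` and `psi` ranges.
#' @param grid_n Scan resolution per axis.
#' @return A data.frame with one row per fixed point: `u`, `psi`, `re1`,
#'   `im1`, `re2`, `im2`, `stability`, `residual`. Zero rows if none found.
#' @export
find_fixed_points <- function(params, variant = "base", I0 = 0,
                              window = list(u = c(0.01, 10), psi = c(-2, 1)),
                              grid_n = 220) {
  stopifnot(inherits(params, "coupled_params"))
  ug <- exp(seq(log(window$u[1]), log(window$u[2]), length.out = grid_n))
  pg <- seq(window$psi[1], window$psi[2], length.out = grid_n)
  UU <- matrix(rep(ug, length(pg)), nrow = length(ug))
  PP <- matrix(rep(pg, each = length(ug)), nrow = length(ug))
  r <- coupled_rhs(as.vector(UU), as.vector(PP), params, I0, variant)
  F1 <- matrix(r$du, nrow = length(ug))
  F2 <- matrix(r$dpsi, nrow = length(ug))
  s1 <- sign(F1); s2 <- sign(F2)
  ## cells where both components change sign across any corner pair
  ch1 <- (s1[-nrow(s1), -ncol(s1)] != s1[-1, -ncol(s1)]) |
         (s1[-nrow(s1), -ncol(s1)] != s1[-nrow(s1), -1]) |
         (s1[-nrow(s1), -ncol(s1)] != s1[-1, -1])
  ch2 <- (s2[-nrow(s2), -ncol(s2)] != s2[-1, -ncol(s2)]) |
         (s2[-nrow(s2), -ncol(s2)] != s2[-nrow(s2), -1]) |
         (s2[-nrow(s2), -ncol(s2)] != s2[-1, -1])
  idx <- which(ch1 & ch2, arr.ind = TRUE)
  roots <- NULL
  for (k in seq_len(nrow(idx))) {
    x <- c(sqrt(ug[idx[k, 1]] * ug[idx[k, 1] + 1L]),
           (pg[idx[k, 2]] + pg[idx[k, 2] + 1L]) / 2)
    x <- newton_polish(x, params, I0, variant)
    rr <- coupled_rhs(max(x[1], 1e-12), x[2], params, I0, variant)
    res <- sqrt(rr$du^2 + rr$dpsi^2)
    if (!is.finite(res) || res > 1e-10) next
    if (x[1] < window$u[1] * 0.5 || x[1] > window$u[2] * 2 ||
        x[2] < window$psi[1] - 0.5 || x[2] > window$psi[2] + 0.5) next
    if (!is.null(roots) &&
        any(abs(roots[, 1] - x[1]) < 1e-6 * (1 + abs(x[1])) &
            abs(roots[, 2] - x[2]) < 1e-6 * (1 + abs(x[2])))) next
    roots <- rbind(roots, c(x, res))
  }
  if (is.null(roots))
    return(data.frame(u = numeric(0), psi = numeric(0), re1 = numeric(0),
                      im1 = numeric(0), re2 = numeric(0), im2 = numeric(0),
                      stability = character(0), residual = numeric(0)))
  out <- lapply(seq_len(nrow(roots)), function(i) {
    J <- coupled_jacobian(roots[i, 1], roots[i, 2], params, I0, variant)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    data.frame(u = roots[i, 1], psi = roots[i, 2],
               re1 = Re(ev[1]), im1 = Im(ev[1]),
               re2 = Re(ev[2]), im2 = Im(ev[2]),
               stability = classify_eigenvalues(ev, det(J)),
               residual = roots[i, 3])
  })
  out <- do.call(rbind, out)
  out[order(out$u), , drop = FALSE]
}

classify_eigenvalues <- function(ev, detJ) {
  if (detJ < 0) return("saddle")
  complex_pair <- any(abs(Im(ev)) > 1e-12)
  stable <- max(Re(ev)) < 0
  if (stable && complex_pair) "stable_focus"
  else if (stable) "stable_node"
  else if (complex_pair) "unstable_focus"
  else "unstable_node"
}

#' Detect a limit cycle by peak-sequence convergence
#'
#' Integrates the coupled system from `init` (default: the unstable region is
#' probed from a small displacement off the first fixed point, or from the
#' `I0 = 0` rest), discards the first `transient_frac` of the horizon, and
#' inspects the remaining calcium peaks: a cycle is reported when at least
#' three peaks exist, the last two inter-peak intervals agree within 1%, the
#' last two peak heights agree within 1%, and the orbit's calcium range
#' exceeds `min_amplitude`.
#'
#' @param params A [coupled_params()] object.
#' @param variant Model variant.
#' @param I0 Inward current.
#' @param init Initial state `c(u, psi)`; default the `I0 = 0` rest.
#' @param horizon Integration length.
#' @param transient_frac Fraction of the horizon discarded as transient.
#' @param min_amplitude Minimal peak-to-trough calcium range for a cycle.
#' @return `NULL` if no cycle; otherwise a list with `period`,
#'   `u_amplitude`, `psi_amplitude`, `n_peaks`, `period_spread`.
#' @export
detect_limit_cycle <- function(params, variant = "base", I0 = 0, init = NULL,
                               horizon = 600, transient_frac = 0.5,
                               min_amplitude = 0.05) {
  if (is.null(init)) {
    r <- rest_state(params, I0 = 0, variant = variant)
    init <- c(r$u, r$psi)
  }
  traj <- simulate_free(params, schedule = I0, init = init,
                        duration = horizon, variant = variant,
                        n_out = max(4001, round(horizon * 20)))
  cut <- traj$eta >= transient_frac * horizon
  u <- traj$u[cut]; eta <- traj$eta[cut]; psi <- traj$psi[cut]
  if (max(u) - min(u) < min_amplitude) return(NULL)
  ipk <- which(diff(sign(diff(u))) < 0) + 1L
  rng <- max(u) - min(u)
  ipk <- ipk[vapply(ipk, function(i)
    (u[i] - max(min(u[seq_len(i)]), min(u[i:length(u)]))) > 0.05 * rng,
    logical(1))]
  if (length(ipk) < 3) return(NULL)
  gaps <- diff(eta[ipk])
  last2 <- utils::tail(gaps, 2)
  spread <- abs(diff(last2)) / mean(last2)
  hspread <- abs(diff(utils::tail(u[ipk], 2))) / max(abs(utils::tail(u[ipk], 2)))
  if (spread > 0.01 || hspread > 0.01) return(NULL)
  list(period = mean(last2),
       u_amplitude = max(u) - min(u),
       psi_amplitude = max(psi) - min(psi),
       n_peaks = length(ipk),
       period_spread = spread)
}

#' Classify the dynamic regime at one inward-current value
#'
#' Labels follow the model's four operating modes:
#' \describe{
#'   \item{`oscillation`}{a limit cycle is detected (the label is used only
#'     when [detect_limit_cycle()] actually returns a cycle).}
#'   \item{`switch`}{the fixed point is stable but relocated to the high-
#'     calcium branch: its calcium exceeds `switch_factor` times the `I0 = 0`
#'     resting calcium and the step response settles there.}
#'   \item{`single_spike`}{a unique stable low-calcium fixed point; the step
#'     response produces at most one transient calcium pulse before
#'     settling.}
#'   \item{`multivibrator`}{(hyper/full variants) the fixed point is unique
#'     and stable at the probed current and at every probe step around it,
#'     and every probe step of either sign produces a single calcium
#'     deflection (at most one interior extremum) that settles at the fixed
#'     point. Probe steps are applied in both directions, matching the idea
#'     that any alteration of the inward current elicits exactly one
#'     impulse.}
#' }
#' `indeterminate` is returned with a diagnostic attribute when none of the
#' rules apply cleanly (e.g. an unstable fixed point without a detectable
#' cycle).
#'
#' @param params A [coupled_params()] object.
#' @param variant Model variant.
#' @param I0 Inward current.
#' @param window Search window for fixed points (wider than the plot window
#'   so high-branch states are found).
#' @param probe_steps Current steps (both signs) used for the multivibrator
#'   probe.
#' @param switch_factor Calcium elevation factor separating `switch` from
#'   `single_spike`.
#' @param spike_factor Calcium elevation factor for counting a transient
#'   pulse in the single-spike probe.
#' @param horizon Simulation horizon for the probes.
#' @return An object of class `regime_report`: list with `mode`,
#'   `fixed_points`, `limit_cycle` and probe diagnostics.
#' @export
classify_regime <- function(params, variant = "base", I0 = 0,
                            window = list(u = c(0.005, 80), psi = c(-3, 4)),
                            probe_steps = c(-0.4, -0.2, 0.2, 0.4),
                            switch_factor = 3, spike_factor = 3,
                            horizon = 400) {
  fps <- find_fixed_points(params, variant, I0, window)
  rest0 <- rest_state(params, I0 = 0, variant = variant)
  report <- function(mode, cycle = NULL, diag = NULL) {
    structure(list(mode = mode, I0 = I0, variant = variant,
                   fixed_points = fps, limit_cycle = cycle,
                   rest = rest0, diagnostics = diag),
              class = "regime_report")
  }
  stable <- fps[grepl("^stable", fps$stability), , drop = FALSE]
  unstable <- fps[!grepl("^stable", fps$stability) &
                    fps$stability != "saddle", , drop = FALSE]

  ## oscillation: an unstable focus/node with a confirmed cycle
  if (nrow(unstable) > 0 && nrow(stable) == 0) {
    cyc <- detect_limit_cycle(params, variant, I0,
                              init = c(rest0$u, rest0$psi), horizon = horizon * 2)
    if (!is.null(cyc)) return(report("oscillation", cycle = cyc))
    return(report("indeterminate",
                  diag = "unstable fixed point but no cycle detected"))
  }
  if (nrow(stable) == 0)
    return(report("indeterminate", diag = "no fixed point found in window"))

  ## multivibrator probe for variants carrying the hyperpolarisation current
  if (variant != "base" && params$vCah > 0 && nrow(stable) == 1 &&
      nrow(fps) == 1) {
    ok <- TRUE; amps <- numeric(0)
    for (dI in probe_steps) {
      fp2 <- find_fixed_points(params, variant, I0 + dI, window)
      st2 <- fp2[grepl("^stable", fp2$stability), , drop = FALSE]
      if (nrow(fp2) != 1 || nrow(st2) != 1) { ok <- FALSE; break }
      base_fp <- rest_state(params, I0 = I0, variant = variant)
      traj <- simulate_free(params, schedule = I0 + dI,
                            init = c(base_fp$u, base_fp$psi),
                            duration = horizon, variant = variant)
      u <- traj$u
      n_ext <- length(interior_extrema(u, prominence = 0.02))
      settled <- abs(u[length(u)] - st2$u) <= 0.05 * max(st2$u, 0.01)
      if (n_ext > 1 || !settled) { ok <- FALSE; break }
      amps <- c(amps, max(abs(u - u[length(u)])))
    }
    if (ok) {
      rep <- report("multivibrator")
      rep$diagnostics <- list(probe_steps = probe_steps, probe_amplitudes = amps)
      return(rep)
    }
  }

  ## stable fixed point: separate switch from single spike by where it sits
  fp <- stable[which.max(abs(stable$re1)), , drop = FALSE]  # unique in practice
  traj <- simulate_free(params, schedule = I0, init = c(rest0$u, rest0$psi),
                        duration = horizon, variant = variant)
  final_u <- traj$u[nrow(traj)]
  peak_u <- max(traj$u)
  if (final_u >= switch_factor * rest0$u)
    return(report("switch",
                  diag = list(final_u = final_u, peak_u = peak_u)))
  m <- spike_metrics(traj)
  if (m$n_extrema <= 1)
    return(report("single_spike",
                  diag = list(final_u = final_u, peak_u = peak_u,
                              pulse = peak_u >= spike_factor * rest0$u,
                              n_extrema = m$n_extrema)))
  report("indeterminate",
         diag = list(final_u = final_u, peak_u = peak_u,
                     n_extrema = m$n_extrema))
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("regime_report: %s at I0 = %g (%s variant), %d fixed point(s)\n",
              x$mode, x$I0, x$variant, nrow(x$fixed_points)))
  if (!is.null(x$limit_cycle))
    cat(sprintf("  limit cycle: period %.3f, u amplitude %.3f\n",
                x$limit_cycle$period, x$limit_cycle$u_amplitude))
  invisible(x)
}

#' Scan the dynamic regime along an inward-current grid
#'
#' Runs [classify_regime()] at each grid value and tabulates the label, the
#' number of fixed points, the stable state and the cycle period.
#'
#' @param params A [coupled_params()] object.
#' @param variant Model variant.
#' @param I0_grid Monotone grid of inward currents.
#' @param ... Passed to [classify_regime()].
#' @return A data.frame with columns `I0`, `mode`, `n_fixed_points`, `u_ss`,
#'   `psi_ss`, `period`.
#' @export
regime_scan <- function(params, variant = "base", I0_grid, ...) {
  rows <- lapply(I0_grid, function(I0) {
    rep <- classify_regime(params, variant, I0, ...)
    st <- rep$fixed_points[grepl("^stable", rep$fixed_points$stability), ,
                           drop = FALSE]
    data.frame(I0 = I0, mode = rep$mode,
               n_fixed_points = nrow(rep$fixed_points),
               u_ss = if (nrow(st)) st$u[1] else NA_real_,
               psi_ss = if (nrow(st)) st$psi[1] else NA_real_,
               period = if (!is.null(rep$limit_cycle))
                 rep$limit_cycle$period else NA_real_)
  })
  do.call(rbind, rows)
}
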