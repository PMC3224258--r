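#' Parameters of the coupled calcium / membrane-potential system
#'
#' The free-membrane (unclamped) model couples the intraciliary calcium
#' balance to the membrane-potential balance:
#' \deqn{du/d\eta = s\,(I_{Ca} - u/(k_A+u) + I_t)}
#' \deqn{d\psi/d\eta = \rho\,(I_{Ca} + I_h + I_K + I_0)}
#' with
#' `I_Ca = -b (c(u) nu(psi) + nuCa_st) (psi - 0.5 log(uout/u))`,
#' `I_K = -b1 (nuK(psi) + vKca * nuK2(psi, u) + nuK_st) (psi - psiK)`,
#' `I_h = +vCah * nuh(psi) * (psi - 0.5 log(uout/u))` (the
#' hyperpolarisation-current term; see the methods vignette for the sign
#' orientation) and `I_t = vCat * nut(psi) * (psi_tr - 0.5 log(u/ut))`
#' (cilium-to-body leak). The gate and all conductances are taken at their
#' voltage/calcium steady states (they relax much faster than `u` and
#' `psi`).
#'
#' Which optional currents act is decided by the `variant` argument of the
#' simulation and analysis functions: `"base"` uses only `I_Ca` and `I_K`;
#' `"hyper"` adds `I_h` and the calcium-dependent potassium contribution;
#' `"full"` further adds `I_t`.
#'
#' @param b Maximal calcium conductance group. Default 8 (coupled-system
#'   tabulated value).
#' @param b1 Potassium conductance group.
#' @param s Calcium flux scale.
#' @param rho Membrane time-scale ratio (`psi` is the fast variable for
#'   `rho >> s`).
#' @param kA Pump half-saturation.
#' @param uout External non-dimensional calcium.
#' @param psiK Potassium reversal potential (non-dimensional). Default -2;
#'   see the methods vignette.
#' @param nuCast,nuKst Voltage-independent background conductances.
#' @param vCah Hyperpolarisation-current scale (0 disables).
#' @param vKca Calcium-dependent potassium conductance scale (0 disables).
#' @param vCat Cilium-to-body conductance scale (0 disables).
#' @param psi_tr Cilium-to-body potential difference.
#' @param ut Cell-body non-dimensional calcium.
#' @param gating An [indirect_gating()] object (the coupled system uses the
#'   sensor-mediated gate).
#' @param ca_cond,k_cond,h_cond,t_cond Conductance voltage dependences.
#' @param pump A [pump_params()] object (overrides `kA` if given).
#' @return An object of class `coupled_params`.
#' @export
coupled_params <- function(b = 8, b1 = 1, s = 0.5, rho = 10,
                           kA = 1, uout = 1000, psiK = -2,
                           nuCast = 0.01, nuKst = 0.01,
                           vCah = 0, vKca = 0, vCat = 0,
                           psi_tr = 0, ut = 0.025,
                           gating = indirect_gating(kC = 1, cac0 = 20),
                           ca_cond = ca_conductance(),
                           k_cond = k_conductance(),
                           h_cond = h_conductance(),
                           t_cond = t_conductance(),
                           pump = NULL) {
  if (is.null(pump)) pump <- pump_params(kA = kA)
  for (nm in c("s", "rho", "uout", "ut")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a single positive number", nm), call. = FALSE)
  }
  for (nm in c("b", "b1", "nuCast", "nuKst", "vCah", "vKca", "vCat")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("%s must be a single non-negative number", nm), call. = FALSE)
  }
  if (!inherits(gating, "indirect_gating"))
    stop("the coupled system uses indirect (sensor-mediated) gating", call. = FALSE)
  structure(list(b = b, b1 = b1, s = s, rho = rho, uout = uout, psiK = psiK,
                 nuCast = nuCast, nuKst = nuKst, vCah = vCah, vKca = vKca,
                 vCat = vCat, psi_tr = psi_tr, ut = ut, gating = gating,
                 ca_cond = ca_cond, k_cond = k_cond, h_cond = h_cond,
                 t_cond = t_cond, pump = pump),
            class = "coupled_params")
}

#' @export
print.coupled_params <- function(x, ...) {
  cat(sprintf(paste0("coupled_params: b = %g, b1 = %g, s = %g, rho = %g, ",
                     "cac0 = %g, psiK = %g, vCah = %g, vKca = %g, vCat = %g\n"),
              x$b, x$b1, x$s, x$rho, x$gating$cac0, x$psiK, x$vCah, x$vKca,
              x$vCat))
  invisible(x)
}

#' Right-hand side of the coupled system
#'
#' Vectorised over the state: `u` and `psi` may be equal-length vectors.
#' The optional currents are included according to `variant`; with their
#' scales at zero the variants reduce to one another exactly.
#'
#' @param u Non-dimensional calcium (> 0).
#' @param psi Non-dimensional potential.
#' @param params A [coupled_params()] object.
#' @param I0 Applied inward current (scalar).
#' @param variant One of `"base"`, `"hyper"`, `"full"`.
#' @return A list with vectors `du`, `dpsi` and the current components
#'   `i_ca`, `i_k`, `i_h`, `i_t`.
#' @export
coupled_rhs <- function(u, psi, params, I0 = 0,
                        variant = c("base", "hyper", "full")) {
  variant <- match.arg(variant)
  if (any(u <= 0)) stop("u must be positive", call. = FALSE)
  g <- params$gating
  cgate <- (g$kC + u) / (g$kC + (g$cac0 + 1) * u)
  drive <- psi - 0.5 * log(params$uout / u)
  i_ca <- -params$b * (cgate * sigmoid_conductance(psi, params$ca_cond) +
                         params$nuCast) * drive
  nuK <- sigmoid_conductance(psi, params$k_cond)
  kfac <- nuK + params$nuKst
  if (variant != "base" && params$vKca > 0)
    kfac <- kfac + params$vKca * nuK * u / (1 + u)
  i_k <- -params$b1 * kfac * (psi - params$psiK)
  i_h <- if (variant != "base" && params$vCah > 0)
    params$vCah * sigmoid_conductance(psi, params$h_cond) * drive
  else rep(0, length(u))
  i_t <- if (variant == "full" && params$vCat > 0)
    params$vCat * sigmoid_conductance(psi, params$t_cond) *
      (params$psi_tr - 0.5 * log(u / params$ut))
  else rep(0, length(u))
  du <- params$s * (i_ca - pump_flux(u, params$pump) + i_t)
  dpsi <- params$rho * (i_ca + i_h + i_k + I0)
  list(du = du, dpsi = dpsi, i_ca = i_ca, i_k = i_k, i_h = i_h, i_t = i_t)
}

#' Piecewise-constant inward-current schedule
#'
#' @param eta Segment start times (first must be 0, strictly increasing).
#' @param I0 Inward-current value on each segment.
#' @return An object of class `current_schedule`.
#' @examples
#' current_schedule(c(0, 50), c(0, 0.3))  # step at eta = 50
#' @export
current_schedule <- function(eta, I0) {
  if (length(eta) != length(I0) || length(eta) < 1)
    stop("eta and I0 must be equal-length, non-empty", call. = FALSE)
  if (eta[1] != 0) stop("the first segment must start at eta = 0", call. = FALSE)
  if (any(diff(eta) <= 0)) stop("segment starts must be strictly increasing",
                                call. = FALSE)
  structure(data.frame(eta = eta, I0 = I0), class = c("current_schedule",
                                                      "data.frame"))
}

schedule_value <- function(schedule, eta) {
  idx <- findInterval(eta, schedule$eta)
  schedule$I0[pmax(idx, 1L)]
}

#' Resting state of the coupled system
#'
#' Finds the stable fixed point by relaxation (long integration from a
#' low-calcium start) followed by Newton polishing; intended for parameter
#' regions with a stable rest state.
#'
#' @param params A [coupled_params()] object.
#' @param I0 Inward current.
#' @param variant Model variant.
#' @param start Starting state for the relaxation.
#' @param settle_time Relaxation horizon.
#' @return Named list with `u`, `psi`, `residual`.
#' @export
rest_state <- function(params, I0 = 0, variant = "base",
                       start = c(u = 0.5, psi = -1.5), settle_time = 500) {
  f <- function(eta, st, p) {
    r <- coupled_rhs(max(st[1], 1e-12), st[2], params, I0, variant)
    list(c(r$du, r$dpsi))
  }
  sol <- deSolve::lsoda(start, c(0, settle_time), f, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  x <- as.numeric(sol[nrow(sol), 2:3])
  x <- newton_polish(x, params, I0, variant)
  r <- coupled_rhs(x[1], x[2], params, I0, variant)
  list(u = x[1], psi = x[2], residual = sqrt(r$du^2 + r$dpsi^2))
}

## Newton iteration on the coupled RHS with a numerical Jacobian.
newton_polish <- function(x, params, I0, variant, max_iter = 50) {
  for (i in seq_len(max_iter)) {
    r <- coupled_rhs(max(x[1], 1e-12), x[2], params, I0, variant)
    f <- c(r$du, r$dpsi)
    if (sqrt(sum(f^2)) < 1e-13) break
    J <- coupled_jacobian(x[1], x[2], params, I0, variant)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    ## damp steps that would leave the positive-u domain
    while (x[1] + step[1] <= 0) step <- step / 2
    x <- x + step
  }
  x
}

#' Numerical Jacobian of the coupled system
#'
#' Central differences of [coupled_rhs()] at a state; used for linear
#' stability classification.
#'
#' @inheritParams coupled_rhs
#' @return A 2x2 matrix d(du, dpsi)/d(u, psi).
#' @export
coupled_jacobian <- function(u, psi, params, I0 = 0, variant = "base") {
  hu <- max(1e-7, 1e-7 * abs(u)); hp <- 1e-7
  fu1 <- coupled_rhs(u + hu, psi, params, I0, variant)
  fu0 <- coupled_rhs(max(u - hu, 1e-12), psi, params, I0, variant)
  fp1 <- coupled_rhs(u, psi + hp, params, I0, variant)
  fp0 <- coupled_rhs(u, psi - hp, params, I0, variant)
  matrix(c((fu1$du - fu0$du) / (2 * hu), (fu1$dpsi - fu0$dpsi) / (2 * hu),
           (fp1$du - fp0$du) / (2 * hp), (fp1$dpsi - fp0$dpsi) / (2 * hp)),
         2, 2)
}

#' Simulate the free-membrane coupled system
#'
#' Integrates the (u, psi) system under a constant inward current or a
#' piecewise-constant [current_schedule()], resampling onto a uniform grid.
#' The default initial state is the resting fixed point at `I0 = 0`, so a
#' schedule that switches to a non-zero current at `eta > 0` reproduces a
#' current-step experiment.
#'
#' @param params A [coupled_params()] object.
#' @param schedule A single `I0` value or a [current_schedule()].
#' @param init Optional initial state `c(u, psi)`; default the `I0 = 0` rest.
#' @param duration Integration horizon (eta units).
#' @param variant Model variant (`"base"`, `"hyper"`, `"full"`).
#' @param n_out Number of output samples.
#' @param rtol,atol Integrator tolerances.
#' @return A `ciliary_trajectory` data.frame with columns
#'   `eta, u, gate, i_ca, i_k, i_full, psi` (gate is the quasi-steady open
#'   fraction `c(u)`; `i_full` is `i_ca + i_h + i_k + I0`, the membrane
#'   balance driving `psi`).
#' @export
simulate_free <- function(params, schedule = 0, init = NULL, duration = 200,
                          variant = c("base", "hyper", "full"),
                          n_out = 4001, rtol = 1e-8, atol = 1e-10) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "coupled_params"))
  if (!inherits(schedule, "current_schedule")) {
    stopifnot(is.numeric(schedule), length(schedule) == 1)
    schedule <- current_schedule(0, schedule)
  }
  if (is.null(init)) {
    r <- rest_state(params, I0 = 0, variant = variant)
    init <- c(u = r$u, psi = r$psi)
  } else {
    init <- c(u = unname(init[1]), psi = unname(init[2]))
  }
  times <- seq(0, duration, length.out = n_out)
  breaks <- schedule$eta[schedule$eta > 0 & schedule$eta < duration]
  segs <- sort(unique(c(0, breaks, duration)))
  out <- NULL
  state <- init
  for (k in seq_len(length(segs) - 1L)) {
    I0k <- schedule_value(schedule, segs[k])
    tt <- unique(c(segs[k], times[times >= segs[k] & times <= segs[k + 1L]],
                   segs[k + 1L]))
    f <- function(eta, st, p) {
      r <- coupled_rhs(max(st[1], 1e-12), st[2], params, I0k, variant)
      list(c(r$du, r$dpsi))
    }
    sol <- deSolve::lsoda(state, tt, f, parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("free-membrane integration failed (stiffness); try tighter tolerances",
           call. = FALSE)
    state <- c(u = unname(sol[nrow(sol), 2]), psi = unname(sol[nrow(sol), 3]))
    keep <- sol[, 1] %in% times & (if (k > 1) sol[, 1] > segs[k] else TRUE)
    seg <- cbind(sol[keep, 1], pmax(sol[keep, 2], 1e-12), sol[keep, 3],
                 schedule_value(schedule, sol[keep, 1]))
    out <- rbind(out, seg)
  }
  u <- out[, 2]; psi <- out[, 3]; I0v <- out[, 4]
  r <- coupled_rhs(u, psi, params, I0v[1], variant)
  ## currents are state functions except for I0, reapplied per sample
  i_full <- r$i_ca + r$i_h + r$i_k + I0v
  traj <- data.frame(eta = out[, 1], u = u,
                     gate = open_fraction_ss(u, params$gating),
                     i_ca = r$i_ca, i_k = r$i_k, i_full = i_full, psi = psi)
  attr(traj, "params") <- params
  attr(traj, "variant") <- variant
  attr(traj, "schedule") <- schedule
  class(traj) <- c("ciliary_trajectory", "data.frame")
  traj
}

#' Current-voltage characteristic from potential-step transients
#'
#' For each step target on the grid, runs the clamp current model with the
#' potassium term included, from the holding-potential rest, and records the
#' transient amplitude of each current (its largest deviation from the final
#' stationary value) together with the stationary full current. A zero-size
#' step therefore reports zero transient amplitudes by construction.
#'
#' @param params A [clamp_params()] object (the tabulated current model uses
#'   `b = 2`, `b1 = 1`).
#' @param psi_grid Monotone grid of step-target potentials.
#' @param psi0 Holding potential.
#' @param tau0,tauK Conductance relaxation times.
#' @param duration Integration horizon per step.
#' @param ... Passed to [simulate_clamp()].
#' @return A data.frame with columns `psi_step`, `peak_i_ca`, `peak_i_k`,
#'   `peak_i_full` (signed deviations from stationary) and
#'   `stationary_i_full`.
#' @export
iv_characteristic <- function(params = clamp_params("direct"), psi_grid,
                              psi0 = -1.2, tau0 = 0.02, tauK = tau0,
                              duration = 40, ...) {
  stopifnot(inherits(params, "clamp_params"))
  rows <- lapply(psi_grid, function(ps) {
    pr <- clamp_protocol(psi0 = psi0, psi1 = ps, tau0 = tau0, tauK = tauK,
                         duration = duration, mechanism = params$mechanism,
                         include_K = TRUE)
    traj <- simulate_clamp(pr, params, ...)
    n <- nrow(traj)
    dev <- function(x) x[which.max(abs(x - x[n]))] - x[n]
    data.frame(psi_step = ps,
               peak_i_ca = dev(traj$i_ca),
               peak_i_k = dev(traj$i_k),
               peak_i_full = dev(traj$i_full),
               stationary_i_full = traj$i_full[n])
  })
  do.call(rbind, rows)
}
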