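#' Voltage-clamp protocol description
#'
#' A clamp run holds the membrane at `psi0` until the coupled
#' (calcium, gate) system is at rest, then steps the potential to `psi1` at
#' `eta = 0`. The calcium conductance relaxes toward its new steady value
#' with time constant `tau0`, the potassium conductance (when included) with
#' `tauK`.
#'
#' @param psi0 Holding potential (non-dimensional). Default -1.2.
#' @param psi1 Step target potential. Default 0.5 (the largest tabulated
#'   depolarising step).
#' @param tau0 Calcium conductance relaxation time (> 0). Default 0.02.
#' @param tauK Potassium conductance relaxation time (> 0). No tabulated
#'   value; defaults to `tau0`.
#' @param duration Integration length in eta units (> 0).
#' @param mechanism `"direct"` (calcium closes its own channel) or
#'   `"indirect"` (closure via the calcium-sensor protein).
#' @param include_K Add the potassium current to the recorded full current.
#' @return An object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(psi0 = -1.2, psi1 = 0.5, tau0 = 0.02, tauK = tau0,
                           duration = 40,
                           mechanism = c("direct", "indirect"),
                           include_K = FALSE) {
  mechanism <- match.arg(mechanism)
  if (!is.finite(tau0) || tau0 <= 0)
    stop("tau0 must be positive (invalid protocol)", call. = FALSE)
  if (!is.finite(tauK) || tauK <= 0)
    stop("tauK must be positive (invalid protocol)", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  structure(list(psi0 = psi0, psi1 = psi1, tau0 = tau0, tauK = tauK,
                 duration = duration, mechanism = mechanism,
                 include_K = include_K),
            class = "clamp_protocol")
}

#' Model parameters for voltage-clamp simulations
#'
#' Collects the non-dimensional groups of the clamp equations: `b` (maximal
#' calcium conductance group), `rate` (the flux-scale prefactor of the
#' calcium balance; tabulated as 0.5 for the direct mechanism and 4 for the
#' indirect one), the pump half-saturation `kA`, the external calcium
#' `uout`, the potassium group `b1` and reversal `psiK`, the gating
#' parameters, and the conductance voltage dependences.
#'
#' @param mechanism `"direct"` or `"indirect"`; fixes the default `rate` and
#'   gating object.
#' @param b Maximal calcium conductance group (> 0).
#' @param rate Flux-scale prefactor of du/deta (> 0). Defaults: 0.5 (direct),
#'   4 (indirect).
#' @param kA Pump half-saturation.
#' @param uout External non-dimensional calcium (> 0).
#' @param b1 Potassium conductance group (>= 0; used when the protocol has
#'   `include_K = TRUE`).
#' @param psiK Potassium reversal potential. Default -2 (see the methods
#'   vignette for the choice; there is no tabulated value).
#' @param gating A [direct_gating()] or [indirect_gating()] object matching
#'   `mechanism`.
#' @param ca_cond,k_cond Conductance voltage dependences.
#' @param pump A [pump_params()] object (overrides `kA` if given).
#' @param cb A [cilium_body_params()] object; `nu_t = 0` disables the
#'   cilium-to-body term (the default for clamp work).
#' @param tcond Voltage dependence of the cilium-to-body conductance.
#' @return An object of class `clamp_params`.
#' @export
clamp_params <- function(mechanism = c("direct", "indirect"),
                         b = 2,
                         rate = NULL,
                         kA = 1,
                         uout = 1000,
                         b1 = 1,
                         psiK = -2,
                         gating = NULL,
                         ca_cond = ca_conductance(),
                         k_cond = k_conductance(),
                         pump = NULL,
                         cb = cilium_body_params(),
                         tcond = t_conductance()) {
  mechanism <- match.arg(mechanism)
  if (is.null(rate)) rate <- if (mechanism == "direct") 0.5 else 4
  if (is.null(gating))
    gating <- if (mechanism == "direct") direct_gating() else indirect_gating()
  if (mechanism == "direct" && !inherits(gating, "direct_gating"))
    stop("direct mechanism requires direct_gating parameters", call. = FALSE)
  if (mechanism == "indirect" && !inherits(gating, "indirect_gating"))
    stop("indirect mechanism requires indirect_gating parameters", call. = FALSE)
  if (is.null(pump)) pump <- pump_params(kA = kA)
  for (nm in c("b", "rate", "uout")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a single positive number", nm), call. = FALSE)
  }
  structure(list(mechanism = mechanism, b = b, rate = rate, uout = uout,
                 b1 = b1, psiK = psiK, gating = gating, ca_cond = ca_cond,
                 k_cond = k_cond, pump = pump, cb = cb, tcond = tcond),
            class = "clamp_params")
}

#' @export
print.clamp_params <- function(x, ...) {
  cat(sprintf("clamp_params (%s mechanism): b = %g, rate = %g, uout = %g, b1 = %g, psiK = %g\n",
              x$mechanism, x$b, x$rate, x$uout, x$b1, x$psiK))
  invisible(x)
}

## Calcium balance at a fixed potential with the gate at its steady state.
## Used for the initial state and for the steady-state curve.
clamp_balance <- function(u, psi, params) {
  gate <- open_fraction_ss(u, params$gating)
  nu <- sigmoid_conductance(psi, params$ca_cond)
  infl <- -params$b * gate * nu * (psi - 0.5 * log(params$uout / u))
  cbterm <- if (params$cb$nu_t > 0)
    cilium_body_current(u, psi, params$cb, params$tcond) else 0
  infl - pump_flux(u, params$pump) + cbterm
}

#' Resting state of the clamp system at a holding potential
#'
#' Solves the calcium balance (passive influx at the holding conductance,
#' against the pump) with the gate at its steady state; the returned state is
#' a fixed point of the clamp equations with residual below `1e-10`.
#'
#' @param params A [clamp_params()] object.
#' @param psi0 Holding potential.
#' @return A named list with `u`, `gate` and the achieved `residual`.
#' @export
clamp_initial_state <- function(params, psi0 = -1.2) {
  stopifnot(inherits(params, "clamp_params"))
  f <- function(u) clamp_balance(u, psi0, params)
  lo <- 1e-10; hi <- 1e6
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop(sprintf(
      "no clamp rest state bracketed in [%g, %g] at psi0 = %g (f(lo) = %g, f(hi) = %g)",
      lo, hi, psi0, flo, fhi), call. = FALSE)
  u0 <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  ## polish with Newton on the balance so the residual is at rounding level
  for (i in 1:8) {
    fu <- f(u0)
    if (abs(fu) < 1e-13) break
    h <- max(1e-9, 1e-8 * u0)
    u0 <- u0 - fu / ((f(u0 + h) - f(u0 - h)) / (2 * h))
  }
  gate0 <- open_fraction_ss(u0, params$gating)
  list(u = u0, gate = gate0, residual = abs(f(u0)))
}

clamp_rhs_factory <- function(params, protocol) {
  nu0 <- sigmoid_conductance(protocol$psi0, params$ca_cond)
  nu1 <- sigmoid_conductance(protocol$psi1, params$ca_cond)
  g <- params$gating
  direct <- params$mechanism == "direct"
  function(eta, state, parms) {
    u <- max(state[1L], 1e-12)
    gate <- state[2L]
    grel <- nu1 - (nu1 - nu0) * exp(-eta / protocol$tau0)
    drive <- protocol$psi1 - 0.5 * log(params$uout / u)
    iCa <- -params$b * gate * grel * drive - pump_flux(u, params$pump)
    du <- iCa
    if (params$cb$nu_t > 0)
      du <- du + cilium_body_current(u, protocol$psi1, params$cb, params$tcond)
    dgate <- if (direct) -g$k * gate * u + (1 - gate)
             else -gate * g$cac0 * u / (g$kC + u) + (1 - gate)
    list(c(params$rate * du, dgate))
  }
}

#' Simulate a voltage-clamp step
#'
#' Integrates the coupled (calcium, gate) system from the holding-potential
#' rest state under a potential step, using a stiff-capable adaptive
#' integrator (relative tolerance 1e-8, absolute 1e-10), and resamples the
#' dense solution onto a uniform grid of `n_out` points.
#'
#' The recorded calcium current is the full non-dimensional calcium balance
#' (passive influx with the relaxing conductance, minus the pump flux); the
#' potassium current (when `include_K`) is
#' `-b1 * nuK_relaxed(eta) * (psi1 - psiK)`; the full current is their sum.
#'
#' @param protocol A [clamp_protocol()] object.
#' @param params A [clamp_params()] object; its mechanism must match the
#'   protocol's.
#' @param n_out Number of output samples (>= 2000 recommended for stable
#'   spike metrics).
#' @param rtol,atol Integrator tolerances.
#' @return A `ciliary_trajectory`: a data.frame with columns
#'   `eta, u, gate, i_ca, i_k, i_full, psi` and the protocol/parameters
#'   stored as attributes.
#' @export
simulate_clamp <- function(protocol, params = clamp_params(protocol$mechanism),
                           n_out = 2001, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "clamp_protocol"), inherits(params, "clamp_params"))
  if (protocol$mechanism != params$mechanism)
    stop("protocol and params disagree on the gating mechanism", call. = FALSE)
  init <- clamp_initial_state(params, protocol$psi0)
  times <- seq(0, protocol$duration, length.out = n_out)
  rhs <- clamp_rhs_factory(params, protocol)
  sol <- deSolve::lsoda(c(u = init$u, gate = init$gate), times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("clamp integration failed (stiffness); try tighter tolerances",
         call. = FALSE)
  u <- pmax(sol[, "u"], 1e-12)
  gate <- sol[, "gate"]
  cur <- clamp_currents(times, u, gate, params, protocol)
  traj <- data.frame(eta = times, u = u, gate = gate,
                     i_ca = cur$i_ca, i_k = cur$i_k, i_full = cur$i_full,
                     psi = rep(protocol$psi1, length(times)))
  attr(traj, "protocol") <- protocol
  attr(traj, "params") <- params
  class(traj) <- c("ciliary_trajectory", "data.frame")
  traj
}

#' Recompute clamp current traces from state series
#'
#' Given the stored time grid, calcium and gate series, rebuilds the current
#' traces from the model equations. Used to verify that stored currents are
#' consistent with the stored state.
#'
#' @param eta Time grid.
#' @param u,gate State series.
#' @param params,protocol Model and protocol objects.
#' @return List with `i_ca`, `i_k`, `i_full` series.
#' @export
clamp_currents <- function(eta, u, gate, params, protocol) {
  nu0 <- sigmoid_conductance(protocol$psi0, params$ca_cond)
  nu1 <- sigmoid_conductance(protocol$psi1, params$ca_cond)
  grel <- nu1 - (nu1 - nu0) * exp(-eta / protocol$tau0)
  drive <- protocol$psi1 - 0.5 * log(params$uout / pmax(u, 1e-12))
  i_ca <- -params$b * gate * grel * drive - pump_flux(pmax(u, 1e-12), params$pump)
  if (isTRUE(protocol$include_K)) {
    nK <- relaxed_conductance(eta,
                              relaxation_spec(protocol$psi0, protocol$psi1,
                                              protocol$tauK),
                              params$k_cond)
    i_k <- -params$b1 * nK * (protocol$psi1 - params$psiK)
  } else {
    i_k <- rep(0, length(eta))
  }
  list(i_ca = i_ca, i_k = i_k, i_full = i_ca + i_k)
}

#' @export
print.ciliary_trajectory <- function(x, ...) {
  cat(sprintf("ciliary_trajectory: %d samples, eta in [%g, %g], u in [%.4g, %.4g]\n",
              nrow(x), min(x$eta), max(x$eta), min(x$u), max(x$u)))
  invisible(x)
}

#' Steady-state calcium as a function of the clamped potential
#'
#' For each potential on the grid, solves the clamp balance with the gate at
#' its steady state. Potentials where no balance exists inside the search
#' bracket are reported as `NA` rather than fabricated.
#'
#' @param params A [clamp_params()] object.
#' @param psi_grid Monotone grid of non-dimensional potentials.
#' @return A data.frame with columns `psi`, `u`, `residual`.
#' @export
steady_state_u <- function(params, psi_grid) {
  stopifnot(inherits(params, "clamp_params"))
  if (is.unsorted(psi_grid) && is.unsorted(rev(psi_grid)))
    stop("psi_grid must be monotone", call. = FALSE)
  res <- vapply(psi_grid, function(psi) {
    st <- tryCatch(clamp_initial_state(params, psi), error = function(e) NULL)
    if (is.null(st)) c(NA_real_, NA_real_) else c(st$u, st$residual)
  }, numeric(2))
  data.frame(psi = psi_grid, u = res[1L, ], residual = res[2L, ])
}

#' Spike metrics of a trajectory
#'
#' Deterministic summary of the calcium response: the pre-step baseline, the
#' peak and its time, the final (post-transient) level, the spike amplitude
#' `peak - final`, and the number of interior maxima. Interior maxima are
#' counted with a prominence filter: a local maximum only counts if it rises
#' above the adjacent troughs by more than `prominence` times the overall
#' trajectory range, which keeps counts stable against integrator-level
#' ripple.
#'
#' @param traj A `ciliary_trajectory` (or any data.frame with `eta` and `u`).
#' @param prominence Relative prominence threshold for counting maxima.
#' @return An object of class `spike_metrics` (named list).
#' @export
spike_metrics <- function(traj, prominence = 0.01) {
  u <- traj$u
  eta <- traj$eta
  n <- length(u)
  ipk <- interior_maxima(u, prominence)
  peak_i <- which.max(u)
  structure(list(baseline = u[1L],
                 peak = u[peak_i],
                 peak_time = eta[peak_i],
                 final_ss = u[n],
                 amplitude = max(u) - u[n],
                 rise = u[peak_i] - u[1L],
                 n_extrema = length(ipk)),
            class = "spike_metrics")
}

## Indices of interior local maxima whose prominence (height above the
## deeper of the flanking minima) exceeds `prominence` times the series
## range. Filters integrator-level ripple out of peak counts.
interior_maxima <- function(u, prominence = 0.01) {
  n <- length(u)
  rng <- max(u) - min(u)
  ipk <- which(diff(sign(diff(u))) < 0) + 1L
  if (rng <= 0 || length(ipk) == 0) return(integer(0))
  keep <- vapply(ipk, function(i) {
    left <- min(u[1:i]); right <- min(u[i:n])
    (u[i] - max(left, right)) > prominence * rng
  }, logical(1))
  ipk[keep]
}

## Interior extrema of either sign, prominence-filtered; the minima are
## counted by mirroring the series.
interior_extrema <- function(u, prominence = 0.01) {
  c(interior_maxima(u, prominence), length(u) + 1L - interior_maxima(rev(-u), prominence))
}

#' @export
print.spike_metrics <- function(x, ...) {
  cat(sprintf(paste0("spike_metrics: baseline %.4g, peak %.4g @ eta %.3g, ",
                     "final %.4g, amplitude %.4g, interior maxima %d\n"),
              x$baseline, x$peak, x$peak_time, x$final_ss, x$amplitude,
              x$n_extrema))
  invisible(x)
}

#' Scan spike metrics over a protocol or parameter grid
#'
#' Runs one clamp simulation per grid value, varying the step target
#' (`psi1`), the external calcium (`uout`) or the holding potential
#' (`psi0`), and collects the spike metrics plus the peak inward current
#' amplitude of each run.
#'
#' @param params A [clamp_params()] object.
#' @param protocol Base [clamp_protocol()]; the varied field is overridden
#'   per grid value.
#' @param vary One of `"psi1"`, `"uout"`, `"psi0"`.
#' @param grid Numeric grid of values for the varied quantity.
#' @param ... Passed to [simulate_clamp()].
#' @return A data.frame with one row per grid value: the grid value, the
#'   spike metrics fields, and `peak_current` (max of |i_ca|).
#' @export
scan_spike_amplitude <- function(params, protocol = clamp_protocol(mechanism = params$mechanism),
                                 vary = c("psi1", "uout", "psi0"), grid, ...) {
  vary <- match.arg(vary)
  rows <- lapply(grid, function(v) {
    pr <- protocol; pa <- params
    if (vary == "uout") pa$uout <- v else pr[[vary]] <- v
    traj <- tryCatch(simulate_clamp(pr, pa, ...), error = function(e) e)
    if (inherits(traj, "error"))
      return(data.frame(value = v, baseline = NA, peak = NA, peak_time = NA,
                        final_ss = NA, amplitude = NA, rise = NA,
                        n_extrema = NA, peak_current = NA,
                        error = conditionMessage(traj)))
    m <- spike_metrics(traj)
    data.frame(value = v, baseline = m$baseline, peak = m$peak,
               peak_time = m$peak_time, final_ss = m$final_ss,
               amplitude = m$amplitude, rise = m$rise,
               n_extrema = m$n_extrema,
               peak_current = max(abs(traj$i_ca)), error = NA_character_)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- vary
  out
}
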