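#' Calcium-dependent calcium-channel gating
#'
#' Two inhibition mechanisms are supported. In the *direct* mechanism a
#' calcium ion binds a site on the channel itself and closes it; the open
#' fraction obeys `dn/deta = -k*n*u + (1 - n)` with steady state
#' `n = 1/(1 + k*u)`. In the *indirect* mechanism calcium first loads a
#' sensor protein whose calcium-bound form closes the channel; the open
#' fraction obeys `dc/deta = -c*cac0*u/(kC + u) + (1 - c)` with steady state
#' `c = (kC + u) / (kC + (cac0 + 1)*u)`, which saturates at the floor
#' `1/(cac0 + 1)` instead of zero: high calcium never closes every channel,
#' and the residue is set by the sensor abundance.
#'
#' @param k Direct mechanism: association ratio `K_CaM / K_C` (positive).
#' @return An object of class `direct_gating` or `indirect_gating` (both
#'   inherit from `gating_params`).
#' @export
direct_gating <- function(k = 2) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("k must be a single positive number", call. = FALSE)
  structure(list(k = k), class = c("direct_gating", "gating_params"))
}

#' @rdname direct_gating
#' @param kC Indirect mechanism: dissociation ratio `K_C / K_CaM` (positive).
#' @param cac0 Indirect mechanism: non-dimensional sensor abundance
#'   `CaC0 / K_CC` (non-negative).
#' @export
indirect_gating <- function(kC = 1, cac0 = 20) {
  if (!is.numeric(kC) || length(kC) != 1 || !is.finite(kC) || kC <= 0)
    stop("kC must be a single positive number", call. = FALSE)
  if (!is.numeric(cac0) || length(cac0) != 1 || !is.finite(cac0) || cac0 < 0)
    stop("cac0 must be a single non-negative number", call. = FALSE)
  structure(list(kC = kC, cac0 = cac0),
            class = c("indirect_gating", "gating_params"))
}

#' Steady-state open fraction of the calcium channels
#'
#' @param u Non-dimensional calcium (vectorised, non-negative).
#' @param gating A [direct_gating()] or [indirect_gating()] object.
#' @return Open fraction(s) in (0, 1].
#' @examples
#' open_fraction_ss(0.5, direct_gating(k = 2))          # 0.5
#' open_fraction_ss(1, indirect_gating(kC = 1, cac0 = 10))  # 2/12
#' @export
open_fraction_ss <- function(u, gating) UseMethod("open_fraction_ss", gating)

#' @export
open_fraction_ss.direct_gating <- function(u, gating) {
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  1 / (1 + gating$k * u)
}

#' @export
open_fraction_ss.indirect_gating <- function(u, gating) {
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  (gating$kC + u) / (gating$kC + (gating$cac0 + 1) * u)
}

#' Time derivative of the gate variable at fixed calcium
#'
#' Right-hand side of the gate relaxation equation; its unique fixed point in
#' the gate variable is [open_fraction_ss()] and is globally attracting (the
#' derivative is strictly decreasing in the gate variable).
#'
#' @param gate Current open fraction (in \[0, 1\]).
#' @param u Non-dimensional calcium (>= 0).
#' @param gating A gating parameter object.
#' @return d(gate)/d(eta).
#' @export
gate_rhs <- function(gate, u, gating) UseMethod("gate_rhs", gating)

#' @export
gate_rhs.direct_gating <- function(gate, u, gating) {
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  -gating$k * gate * u + (1 - gate)
}

#' @export
gate_rhs.indirect_gating <- function(gate, u, gating) {
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  -gate * gating$cac0 * u / (gating$kC + u) + (1 - gate)
}

#' Closed-form indirect gate response to a calcium step
#'
#' After calcium jumps from `u0` to `u1` the open fraction relaxes
#' exponentially between the two steady fractions,
#' `c(eta) = c_inf - (c_inf - c0) * exp(-eta / tau)`, with the characteristic
#' time given by [gate_time_constant()].
#'
#' @param eta Non-dimensional time(s), >= 0.
#' @param u0 Calcium before the step.
#' @param u1 Calcium after the step.
#' @param gating An [indirect_gating()] object.
#' @return Open fraction(s) along `eta`.
#' @export
gate_analytic <- function(eta, u0, u1, gating) {
  stopifnot(inherits(gating, "indirect_gating"))
  if (any(eta < 0)) stop("eta must be non-negative", call. = FALSE)
  c0 <- open_fraction_ss(u0, gating)
  cinf <- open_fraction_ss(u1, gating)
  cinf - (cinf - c0) * exp(-eta / gate_time_constant(u1, gating))
}

#' Characteristic time of the indirect gate response
#'
#' `tau = (kC + u1) / (kC + (cac0 + 1) * u1)` in eta units; equals 1 at
#' `u1 = 0` and approaches `1/(cac0 + 1)` for calcium far above both `kC`
#' and `1/cac0`.
#'
#' @param u1 Post-step calcium (>= 0, vectorised).
#' @param gating An [indirect_gating()] object.
#' @return Time constant(s) in eta units.
#' @export
gate_time_constant <- function(u1, gating) {
  stopifnot(inherits(gating, "indirect_gating"))
  if (any(u1 < 0)) stop("u1 must be non-negative", call. = FALSE)
  (gating$kC + u1) / (gating$kC + (gating$cac0 + 1) * u1)
}

#' Active-transport pump parameters
#'
#' The plasma-membrane calcium pump saturates with the Michaelis form
#' `u / (kA + u)`. An optional kinetic mode tracks the bound-pump fraction
#' `omega` through `d(omega)/d(eta) = ka*u*(1 - omega) - kb*omega`, whose
#' steady state reproduces the Michaelis flux when `kA = kb/ka`.
#'
#' @param kA Half-saturation constant (positive).
#' @param ka,kb Optional binding/turnover rates for the kinetic mode.
#' @return An object of class `pump_params`.
#' @export
pump_params <- function(kA = 1, ka = NULL, kb = NULL) {
  if (!is.numeric(kA) || length(kA) != 1 || !is.finite(kA) || kA <= 0)
    stop("kA must be a single positive number", call. = FALSE)
  if (xor(is.null(ka), is.null(kb)))
    stop("supply both ka and kb for kinetic mode, or neither", call. = FALSE)
  structure(list(kA = kA, ka = ka, kb = kb), class = "pump_params")
}

#' Steady-state pump flux
#'
#' @param u Non-dimensional calcium (vectorised, >= 0).
#' @param params A [pump_params()] object.
#' @return Saturating flux `u / (kA + u)` in (0, 1).
#' @export
pump_flux <- function(u, params = pump_params()) {
  stopifnot(inherits(params, "pump_params"))
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  u / (params$kA + u)
}

#' @describeIn pump_params Kinetic right-hand side for the bound fraction.
#' @param omega Bound-pump fraction in \[0, 1\].
#' @param u Non-dimensional calcium.
#' @param params A `pump_params` object with `ka`, `kb` set.
#' @export
pump_kinetic_rhs <- function(omega, u, params) {
  stopifnot(inherits(params, "pump_params"))
  if (is.null(params$ka))
    stop("pump_params was built without kinetic rates ka, kb", call. = FALSE)
  params$ka * u * (1 - omega) - params$kb * omega
}

#' Cilium-to-body leak parameters and current
#'
#' The calcium current from the ciliary compartment into the cell body is a
#' Nernst-driven leak through the transition-zone conductance:
#' `I_t = nu_t * nu_t(psi) * (psi_tr - 0.5 * log(u / ut))`, zero exactly when
#' the potential difference `psi_tr` balances the calcium gradient.
#'
#' `ut` (non-dimensional cell-body calcium) has no tabulated value; the
#' default 0.025 corresponds to 0.1 uM, one order of magnitude below a
#' typical intraciliary resting level.
#'
#' @param nu_t Conductance scale (>= 0; 0 disables the current).
#' @param psi_tr Cilium-to-body potential difference (non-dimensional).
#' @param ut Non-dimensional cell-body calcium (positive).
#' @return An object of class `cilium_body_params`.
#' @export
cilium_body_params <- function(nu_t = 0, psi_tr = 0, ut = 0.025) {
  if (!is.numeric(ut) || length(ut) != 1 || !is.finite(ut) || ut <= 0)
    stop("ut must be a single positive number", call. = FALSE)
  if (nu_t < 0) stop("nu_t must be non-negative", call. = FALSE)
  structure(list(nu_t = nu_t, psi_tr = psi_tr, ut = ut),
            class = "cilium_body_params")
}

#' @describeIn cilium_body_params Evaluate the cilium-to-body current at
#'   calcium `u` and potential `psi` with the voltage dependence `tcond`.
#' @param u Intraciliary non-dimensional calcium (> 0).
#' @param psi Non-dimensional membrane potential.
#' @param params A `cilium_body_params` object.
#' @param tcond A [conductance_params()] object for the voltage dependence
#'   (default [t_conductance()]).
#' @export
cilium_body_current <- function(u, psi, params, tcond = t_conductance()) {
  stopifnot(inherits(params, "cilium_body_params"))
  if (any(u <= 0)) stop("u must be positive (log singularity at 0)", call. = FALSE)
  params$nu_t * sigmoid_conductance(psi, tcond) *
    (params$psi_tr - 0.5 * log(u / params$ut))
}
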