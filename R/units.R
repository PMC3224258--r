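#' Physical constants for the non-dimensional scales
#'
#' The model works in non-dimensional variables: calcium as
#' `u = [Ca2+] / K_CaM` (with `K_CaM` the calmodulin dissociation scale) and
#' membrane potential as `psi = F * V / (R * T)`. This constructor holds the
#' two conversion constants and the calcium ion charge.
#'
#' The default `RT_over_F = -0.025` V follows the model's own sign convention
#' for the potential scale: it is the only mapping under which the standard
#' non-dimensional holding and step potentials (psi = -1.2, -1, ..., 0.5)
#' correspond to the tabulated millivolt values (30, 25, ..., -12.5 mV).
#'
#' @param K_CaM Calmodulin calcium dissociation scale, in micromolar.
#' @param RT_over_F Thermal voltage R*T/F in volts (signed).
#' @param z Ion charge (2 for calcium).
#' @return An object of class `ciliary_constants`.
#' @examples
#' cc <- ciliary_constants()
#' to_psi(25, cc)     # -1
#' to_uM(10, cc)      # 40
#' @export
ciliary_constants <- function(K_CaM = 4, RT_over_F = -0.025, z = 2L) {
  if (!is.numeric(K_CaM) || length(K_CaM) != 1 || !is.finite(K_CaM) || K_CaM <= 0)
    stop("K_CaM must be a single positive number (uM)", call. = FALSE)
  if (!is.numeric(RT_over_F) || length(RT_over_F) != 1 || !is.finite(RT_over_F) ||
      RT_over_F == 0)
    stop("RT_over_F must be a single non-zero number (V)", call. = FALSE)
  structure(list(K_CaM = K_CaM, RT_over_F = RT_over_F, z = as.integer(z)),
            class = "ciliary_constants")
}

#' @export
print.ciliary_constants <- function(x, ...) {
  cat("ciliary_constants: K_CaM =", x$K_CaM, "uM, RT/F =", x$RT_over_F,
      "V, z =", x$z, "\n")
  invisible(x)
}

#' Convert a membrane potential in millivolts to the non-dimensional psi
#'
#' `psi = V / (RT/F)` with `RT/F` expressed in millivolts.
#'
#' @param V_mV Membrane potential in mV (vectorised).
#' @param constants A [ciliary_constants()] object.
#' @return Non-dimensional potential(s).
#' @export
to_psi <- function(V_mV, constants = ciliary_constants()) {
  stopifnot(inherits(constants, "ciliary_constants"))
  V_mV / (constants$RT_over_F * 1000)
}

#' Convert a non-dimensional potential to millivolts
#'
#' Inverse of [to_psi()]; round-trips exactly.
#'
#' @param psi Non-dimensional potential (vectorised).
#' @param constants A [ciliary_constants()] object.
#' @return Potential(s) in mV.
#' @export
to_mV <- function(psi, constants = ciliary_constants()) {
  stopifnot(inherits(constants, "ciliary_constants"))
  psi * (constants$RT_over_F * 1000)
}

#' Convert a calcium concentration in micromolar to non-dimensional u
#'
#' `u = [Ca2+] / K_CaM`.
#'
#' @param ca_uM Calcium concentration in uM (vectorised, non-negative).
#' @param constants A [ciliary_constants()] object.
#' @return Non-dimensional calcium value(s).
#' @export
to_u <- function(ca_uM, constants = ciliary_constants()) {
  stopifnot(inherits(constants, "ciliary_constants"))
  if (any(ca_uM < 0, na.rm = TRUE))
    stop("calcium concentration must be non-negative", call. = FALSE)
  ca_uM / constants$K_CaM
}

#' Convert non-dimensional calcium u to micromolar
#'
#' Inverse of [to_u()]; round-trips exactly.
#'
#' @param u Non-dimensional calcium (vectorised, non-negative).
#' @param constants A [ciliary_constants()] object.
#' @return Concentration(s) in uM.
#' @export
to_uM <- function(u, constants = ciliary_constants()) {
  stopifnot(inherits(constants, "ciliary_constants"))
  if (any(u < 0, na.rm = TRUE))
    stop("non-dimensional calcium must be non-negative", call. = FALSE)
  u * constants$K_CaM
}
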