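#' Sigmoid voltage dependence of a channel family's conductance
#'
#' All four channel families (calcium, potassium, hyperpolarisation-activated,
#' cilium-to-body) share one functional form for the normalised steady-state
#' conductance,
#' \deqn{\nu(\psi) = \frac{e^{\alpha(\psi+d)}}{\lambda + e^{\alpha(\psi+d)}},}
#' a bounded sigmoid in the non-dimensional potential. `alpha` sets the
#' steepness (and, through its sign, the activation direction), `d` the
#' offset and `lambda` the scale; the half-activation point sits at
#' `psi = log(lambda)/alpha - d`.
#'
#' @param alpha Steepness (non-zero).
#' @param d Offset.
#' @param lambda Scale (must be positive for a bounded sigmoid).
#' @return An object of class `conductance_params`.
#' @seealso [sigmoid_conductance()], [ca_conductance()]
#' @export
conductance_params <- function(alpha, d, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha))
    stop("alpha must be a single finite number", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d))
    stop("d must be a single finite number", call. = FALSE)
  structure(list(alpha = alpha, d = d, lambda = lambda),
            class = "conductance_params")
}

#' @export
print.conductance_params <- function(x, ...) {
  cat(sprintf("conductance_params: alpha = %g, d = %g, lambda = %g\n",
              x$alpha, x$d, x$lambda))
  invisible(x)
}

#' Default conductance parameter sets for the four channel families
#'
#' Tabulated defaults: calcium (4, 0.4, 0.5); potassium (0.5, 0.5, 0.005);
#' hyperpolarisation-activated (4, 1, 5). The cilium-to-body family has no
#' tabulated triple; it mirrors the hyperpolarisation family with the
#' steepness negated so that its conductance grows under hyperpolarisation.
#'
#' @param alpha,d,lambda Override individual entries.
#' @return A `conductance_params` object.
#' @export
ca_conductance <- function(alpha = 4, d = 0.4, lambda = 0.5)
  conductance_params(alpha, d, lambda)

#' @rdname ca_conductance
#' @export
k_conductance <- function(alpha = 0.5, d = 0.5, lambda = 0.005)
  conductance_params(alpha, d, lambda)

#' @rdname ca_conductance
#' @export
h_conductance <- function(alpha = 4, d = 1, lambda = 5)
  conductance_params(alpha, d, lambda)

#' @rdname ca_conductance
#' @export
t_conductance <- function(alpha = -4, d = 1, lambda = 5)
  conductance_params(alpha, d, lambda)

#' Evaluate the steady-state sigmoid conductance
#'
#' Returns `exp(alpha*(psi+d)) / (lambda + exp(alpha*(psi+d)))`, a fraction in
#' (0, 1), strictly monotone in `psi` (increasing iff `alpha > 0`). The
#' exponential is clamped at |argument| > 700 and replaced by the exact
#' asymptote, so extreme potentials never produce NaN or Inf.
#'
#' @param psi Non-dimensional potential (vectorised).
#' @param params A [conductance_params()] object.
#' @return Conductance fraction(s) in (0, 1).
#' @examples
#' sigmoid_conductance(0, ca_conductance())  # 0.9083
#' @export
sigmoid_conductance <- function(psi, params) {
  stopifnot(inherits(params, "conductance_params"))
  x <- params$alpha * (psi + params$d)
  out <- numeric(length(x))
  hi <- x > 700
  lo <- x < -700
  mid <- !hi & !lo
  out[hi] <- 1
  out[lo] <- 0
  ex <- exp(x[mid])
  out[mid] <- ex / (params$lambda + ex)
  out
}

#' Exponential relaxation of a conductance between two clamped potentials
#'
#' Under a voltage-clamp step from `psi0` to `psi1` the conductance does not
#' switch instantaneously: it relaxes exponentially from its steady value at
#' the holding potential to its steady value at the step target,
#' \deqn{\nu(\eta) = \nu(\psi_1) - (\nu(\psi_1) - \nu(\psi_0))\, e^{-\eta/\tau}.}
#'
#' @param psi0 Holding potential (non-dimensional).
#' @param psi1 Step target potential.
#' @param tau Relaxation time constant in eta units (positive).
#' @return An object of class `relaxation_spec`.
#' @export
relaxation_spec <- function(psi0, psi1, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("relaxation time constant tau must be positive", call. = FALSE)
  structure(list(psi0 = psi0, psi1 = psi1, tau = tau), class = "relaxation_spec")
}

#' @describeIn relaxation_spec Evaluate the relaxing conductance at times
#'   `eta >= 0` for the channel family described by `params`.
#' @param eta Non-dimensional time(s), >= 0.
#' @param spec A `relaxation_spec`.
#' @param params A [conductance_params()] object.
#' @export
relaxed_conductance <- function(eta, spec, params) {
  stopifnot(inherits(spec, "relaxation_spec"))
  if (any(eta < 0)) stop("eta must be non-negative", call. = FALSE)
  n0 <- sigmoid_conductance(spec$psi0, params)
  n1 <- sigmoid_conductance(spec$psi1, params)
  n1 - (n1 - n0) * exp(-eta / spec$tau)
}
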