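# Shared fixtures: the tabulated parameter sets used throughout the suite.

tab_clamp_direct <- function(alpha = 4, ...) {
  clamp_params("direct", b = 2, rate = 0.5,
               gating = direct_gating(k = 2),
               ca_cond = conductance_params(alpha, 0.4, 0.5), ...)
}

tab_clamp_indirect <- function(cac0 = 20, ...) {
  clamp_params("indirect", b = 2, rate = 4,
               gating = indirect_gating(kC = 1, cac0 = cac0), ...)
}

tab_coupled <- function(...) {
  coupled_params(b = 8, b1 = 1, s = 0.5, rho = 10,
                 gating = indirect_gating(kC = 1, cac0 = 20),
                 nuCast = 0.01, nuKst = 0.01, ...)
}

psi1_grid <- c(-1, -0.8, -0.5, -0.2, 0, 0.2, 0.5)

# independent re-implementation of the clamp right-hand side used as an
# oracle for current recomputation and Jacobian checks
oracle_clamp_rhs <- function(eta, u, gate, params, protocol) {
  nu <- function(psi) sigmoid_conductance(psi, params$ca_cond)
  grel <- nu(protocol$psi1) -
    (nu(protocol$psi1) - nu(protocol$psi0)) * exp(-eta / protocol$tau0)
  drive <- protocol$psi1 - 0.5 * log(params$uout / u)
  i <- -params$b * gate * grel * drive - u / (params$pump$kA + u)
  g <- params$gating
  dgate <- if (inherits(g, "direct_gating")) -g$k * gate * u + (1 - gate)
           else -gate * g$cac0 * u / (g$kC + u) + (1 - gate)
  c(params$rate * i, dgate)
}
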