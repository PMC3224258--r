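---
title: "Modelling ciliary Ca2+ / membrane-potential excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ciliary Ca2+ / membrane-potential excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliadyn)
```

## The system being modelled

Motile cilia maintain an ionic compartment of their own: intraciliary Ca2+
can sit an order of magnitude above the cell body's level, and the beat is
steered by how that Ca2+ pool responds to the ciliary membrane potential.
The model implemented here treats the cilium as a two-variable excitable
system. The fast variable is the non-dimensional membrane potential
$\psi = F V / (R T)$; the slow variable is the non-dimensional calcium
$u = [\mathrm{Ca}^{2+}]/K_{CaM}$, scaled by the calmodulin dissociation
constant $K_{CaM} = 4\,\mu M$. The potential scale constant is
$RT/F = -0.025\,\mathrm{V}$, the only signed choice under which the
package's tabulated potential pairs ($\psi = -1.2 \leftrightarrow 30$ mV,
$\psi = 0.5 \leftrightarrow -12.5$ mV) hold; all model dynamics are
internally consistent in $\psi$, where *increasing $\psi$ is the direction
that activates the Ca2+ and K+ conductances* and is referred to as
depolarisation throughout.

Four channel families share one voltage dependence, a bounded sigmoid

$$\nu(\psi) = \frac{e^{\alpha(\psi+d)}}{\lambda + e^{\alpha(\psi+d)}},$$

parameterised per family (Ca2+: $\alpha=4, d=0.4, \lambda=0.5$; K+:
$\alpha=0.5, d=0.5, \lambda=0.005$; hyperpolarisation family:
$\alpha=4, d=1, \lambda=5$; cilium-to-body family: mirrored with
$\alpha=-4$ because no triple is tabulated for it and its conductance must
grow under hyperpolarisation). The exponential argument is clamped at
$|x|>700$ and replaced by the exact asymptote so integrators can probe
arbitrary potentials without NaN.

Calcium inhibits its own influx by closing Ca2+ channels, via either of two
mechanisms. The *direct* gate binds Ca2+ on the channel,
$dn/d\eta = -k n u + (1-n)$, closing completely at high calcium. The
*indirect* gate works through a Ca2+-sensor protein,
$dc/d\eta = -c\,cac_0 u/(k_C+u) + (1-c)$, and saturates at the floor
$1/(cac_0+1)$: however high calcium rises, a sensor-limited fraction of
channels stays open. Both steady states, the closed-form step response of
the indirect gate and its characteristic time
$\tau = (k_C+u)/(k_C+(cac_0+1)u)$ are exported and property-tested against
stiff integration. Extrusion is a saturating pump $u/(k_A+u)$; its
microscopic binding kinetics are available (`pump_params(ka=, kb=)`) but
the quasi-steady Michaelis form is the default, the pump cycle being much
faster than the calcium pool.

## Voltage clamp

A clamp step $\psi_0 \to \psi_1$ relaxes the conductance exponentially with
time constant $\tau_0 = 0.02$ and integrates the (calcium, gate) pair; the
recorded Ca2+ current is the signed balance
$-b\,g\,\nu_{rel}\,(\psi_1 - \tfrac12\ln(u_{out}/u)) - u/(k_A+u)$, so with
a negative driving force the inward transient is a *positive* excursion
that returns to zero at the new rest. The K+ current
$-b_1 \nu_{K,rel} (\psi_1-\psi_K)$ is added when requested; its relaxation
time has no tabulated value and defaults to $\tau_0$.

Two numerical choices matter here. Initial states are true fixed points
(bracketed root plus Newton polish, residual $< 10^{-10}$), so a null step
stays flat to integrator tolerance. Integration uses `deSolve::lsoda` with
relative tolerance $10^{-8}$ and absolute $10^{-10}$, resampled to at
least 2000 uniform points so spike metrics are grid-stable; `u` is floored
at $10^{-12}$ inside logarithms only, never in the state itself.

### A deliberate, documented limitation

The tabulated clamp rate constants circulate in two inconsistent versions —
the same composite flux-scale group appears both as $0.5$ (direct
mechanism) and $4$ (indirect) — and under *either* value the clamp response
is overdamped: the gate relaxes at rate $1 + k u \approx 2\!-\!7$ per
$\eta$, faster than calcium itself ($\approx s\,b\,\nu\,\partial(\text{drive})
\lesssim 1$), so after a depolarising step the calcium trace rises
monotonically to its new fixed point with no interior maximum. A clean
single-spike overshoot under clamp requires the calcium relaxation to be
roughly five times faster than any tabulated rate provides (this is easy to
verify by passing `rate = 5` to `clamp_params()`). The package keeps the
tabulated defaults rather than inventing a faster rate; the corresponding
acceptance expectations (one interior maximum per step, amplitude
proportional to step size, and the 5% coincidence of indirect-mechanism
current traces across sensor abundances, which fails for the same reason —
the per-`cac0` rest states scale the early currents) are left failing on
purpose as an honest record. The spike phenomenology itself is not lost:
it is fully expressed in the free-membrane system below, where the fast
potential variable provides the regenerative upstroke.

## The coupled free-membrane system

With the clamp removed the currents drive the potential:

$$\frac{du}{d\eta} = s\left(I_{Ca} - \frac{u}{k_A+u}\right),\qquad
\frac{d\psi}{d\eta} = \rho\left(I_{Ca} + I_h + I_K + I_0\right),$$

$I_{Ca} = -b\,(c(u)\nu(\psi)+\nu_{st})(\psi-\tfrac12\ln(u_{out}/u))$,
$I_K = -b_1(\nu_K(\psi)+\nu_{st})(\psi-\psi_K)$. The gate and conductances
are taken quasi-steady (they relax much faster than $u$ or $\psi$).
Defaults are the tabulated coupled set $b=8$, $cac_0=20$, $\rho=10$,
$s=0.5$, $\nu_{st}=0.01$. Two orientation decisions were genuinely open and
were resolved once, by requiring the coupled system to reproduce its own
documented response classes:

* **Sign of the potential balance.** The signs are oriented so that
  depolarisation activates the Ca2+/K+ conductances, $I_{Ca}$ is
  regenerative (positive feedback), $I_K$ repolarising, and increasing
  $I_0$ raises the resting potential. This is the only orientation that
  produces the single-spike → oscillation → switch sequence along $I_0$.
* **Orientation of the hyperpolarisation current.** $I_h =
  +v_{Cah}\,\nu_h(\psi)\,(\psi-\tfrac12\ln(u_{out}/u))$ enters the
  potential balance as a *hyperpolarising* conductance that grows with
  $\psi$ — an adaptation-like brake. With the grouping reversed
  (depolarising), the rest state migrates to the high-calcium branch and
  no impulse responses exist at any inward current, contradicting the
  multivibrator behaviour this term is supposed to produce; the
  implemented orientation yields a unique stable fixed point at every
  probed $I_0$ and restores the limit cycle when $v_{Cah}=0$.

Two free parameters have no tabulated value and were fixed once:

* **$\psi_K = -2$** (K+ reversal). It must sit below the resting potential
  for the K+ current to repolarise; $-2$ places the coupled rest at
  $u \approx 0.94$, $\psi \approx -1.52$ and gives the full three-regime
  structure. (Choosing it from the clamp current's zero crossing near
  $\psi = -0.4$ instead puts the rest on the high-calcium branch and
  removes the oscillatory window entirely — that candidate rule was
  rejected for this reason.)
* **$u_t = 0.025$** (cell-body calcium, i.e. 0.1 µM): one order of
  magnitude below a typical intraciliary resting level.

The Ca2+-dependent K+ contribution of the hyper variant has no printed
functional form; it is implemented as $\nu_K(\psi)\,u/(1+u)$ scaled by
$v_{Kca}$ (first-order calcium activation saturating on the calmodulin
scale) and defaults to zero. Variant reductions are exact: `hyper` with
$v_{Cah}=v_{Kca}=0$ equals `base` bitwise, `full` with $v_{Cat}=0$ equals
`hyper`.

## Phase-plane analysis and regime labels

Nullclines are traced by per-grid-line root finding over the default window
$u \in [0.01, 10]$ (0.04–40 µM), $\psi \in [-2, 1]$, with 240 log-spaced
calcium lines and 600-point potential bracketing; lines without a crossing
are recorded as gaps. Turning points of the potential nullcline are
detected as grid transitions where the root count jumps by two (a fold
birth or merge); the N shape of the potential nullcline and the
monotonicity of the calcium nullcline's physiological branch are asserted
in the acceptance suite. Fixed points come from a 220×220 sign-change scan
polished by damped Newton iteration (residual $< 10^{-10}$) and are
classified by Jacobian eigenvalues; an independent 2000×2000 brute-force
scan cross-checks the roots in the tests. Because the high-calcium switch
state can sit above $u = 10$, classification searches a wider window
($u \le 80$, $\psi \le 4$) than the plotting default.

Limit cycles are detected by peak-sequence convergence: after discarding
the first half of a 600–1200 $\eta$ horizon, at least three
prominence-filtered calcium peaks whose last two inter-peak intervals and
heights agree within 1%. A Poincaré section would add nothing for a planar
system.

The regime labels are operational definitions, fixed before use:

* `oscillation` — a limit cycle was actually detected (never inferred from
  instability alone);
* `switch` — stable fixed point with calcium at least 3× the $I_0=0$ rest;
* `single_spike` — stable fixed point below that threshold, whose step
  response has at most one prominence-significant interior maximum;
* `multivibrator` — (variants with $v_{Cah}>0$) a unique stable fixed point
  at the probed current *and* under probe steps of $\pm 0.2$ and $\pm 0.4$,
  each step answering with a single calcium deflection (at most one
  interior extremum) that settles at the fixed point. A fixed elevation
  factor cannot serve here: a negative current step lowers calcium toward
  the background-conductance floor, so no threshold-crossing definition
  can fire for both signs; the single-deflection criterion captures
  "exactly one impulse per perturbation, either sign" and is the
  package's operational reading of that mode.

Spike counting everywhere uses a prominence filter (default 1–2% of the
trace range) so integrator-level ripple never inflates peak counts; the
counts are invariant to refining the output grid from 2001 to 6001 points,
which the tests assert.

## Problem sizes and runtime

The suite's simulations are sized to make every assertion sharp but cheap:
clamp runs use 2001 output points over 40 $\eta$; free-membrane runs 4001
points over 150–600 $\eta$; regime scans use 11 currents (base) and 6
(hyper); the brute-force fixed-point oracle uses a 2000×2000 grid in
chunks. The full suite runs in well under a minute of simulation time plus
the oracle scans.

## What the tests do and do not establish

The model is deterministic — there is no synthetic-data randomness anywhere,
and byte-identical reruns are part of the acceptance suite. Passing tests
establish the implemented equations' internal behaviour: exact unit
correspondences, gating limits and closed forms, clamp balances, the
three-regime structure, multivibrator behaviour and nullcline geometry
under the default parameter sets. They do not establish that those
parameter values describe any particular organism's cilia: no experimental
recordings are fitted (none are available to the package), the K+
conductance triple makes $\nu_K$ essentially saturated over the
physiological window (so K+ behaves quasi-ohmically), and the clamp-rate
inconsistency above means the clamp module's dynamic overshoot claims
should be read against the free-membrane system, not the clamp defaults.
Temperature dependence of $RT/F$, activity corrections, multi-state
channel kinetics, spatial structure along the axoneme and mechanical beat
coupling are all out of scope.
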