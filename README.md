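# ciliadyn

Conductance-based modelling of the motile cilium as an excitable system:
intraciliary Ca²⁺ concentration coupled to the ciliary membrane potential.

Motile cilia keep their own Ca²⁺ compartment, and the interplay between
voltage-dependent Ca²⁺ influx, Ca²⁺-dependent inhibition of the Ca²⁺
channels, K⁺ currents and active Ca²⁺ extrusion makes the cilium electrically
excitable in a way that differs from classical neuronal excitability: the
depolarisation-activated Ca²⁺ current is throttled by the very Ca²⁺ it
admits. `ciliadyn` implements this model for researchers studying ciliary
beat regulation, and for anyone who wants a compact, well-tested
two-variable excitable system with a biophysically grounded phase plane.

## The model

All computation is non-dimensional: calcium is `u = [Ca²⁺]/K_CaM`
(`K_CaM = 4 µM`), potential is `ψ = F·V/(R·T)` (`RT/F = −0.025 V`, so
`ψ = −1.2` corresponds to the tabulated 30 mV). Each channel family has a
sigmoid steady-state conductance

    ν(ψ) = exp(α(ψ+d)) / (λ + exp(α(ψ+d)))

Under voltage clamp, a step `ψ₀ → ψ₁` drives

    du/dη = rate · ( −b·g(η)·ν_rel(η)·(ψ₁ − ½ ln(u_out/u)) − u/(k_A+u) )

with `g` the open-channel fraction — either the direct gate
(`dn/dη = −k·n·u + (1−n)`, steady state `1/(1+k·u)`) or the sensor-mediated
gate (`dc/dη = −c·cac₀·u/(k_C+u) + (1−c)`, steady state
`(k_C+u)/(k_C+(cac₀+1)·u)`, which saturates at the floor `1/(cac₀+1)`) —
and `ν_rel` the exponentially relaxing conductance.

Free of the clamp, potential and calcium form the coupled system

    du/dη = s·( I_Ca − u/(k_A+u) )
    dψ/dη = ρ·( I_Ca + I_h + I_K + I₀ )

with `I_Ca = −b·(c(u)·ν(ψ)+ν_st)·(ψ − ½ ln(u_out/u))`,
`I_K = −b₁·(ν_K(ψ)+ν_st)·(ψ − ψ_K)`, an optional
hyperpolarisation-current term `I_h` and a cilium-to-body leak. Depending
on the applied inward current `I₀` the system rests, fires a single Ca²⁺
spike, oscillates on a limit cycle, or switches to a high-Ca²⁺ state; with
the hyperpolarisation current enabled it becomes a monostable multivibrator
that answers every change of `I₀` with exactly one impulse. The phase-plane
layer computes nullclines, fixed points with eigenvalue stability, limit
cycles and these regime labels.

## Worked example

```r
library(ciliadyn)

## resting state of the coupled system (b = 8, cac0 = 20, rho = 10, s = 0.5)
p <- coupled_params()
rest_state(p, I0 = 0)
#> $u        0.9390157   # 3.76 uM on the K_CaM scale
#> $psi     -1.516575    # ~38 mV on the tabulated potential scale
#> $residual 1.87e-14

## a small inward-current step fires one Ca2+ pulse
tr <- simulate_free(p, schedule = current_schedule(c(0, 20), c(0, 0.2)),
                    duration = 300)
max(tr$u)
#> [1] 3.058918          # peak of the pulse, then return toward rest

## the regime map along the inward current
regime_scan(p, "base", c(0.1, 0.3, 0.5, 1))
#>    I0         mode n_fixed_points      u_ss     psi_ss   period
#> 1 0.1 single_spike              1  1.048444 -1.3895548       NA
#> 2 0.3 single_spike              1  1.788198 -1.0618646       NA
#> 3 0.5  oscillation              1        NA         NA 19.52622
#> 4 1.0       switch              1 15.551469 -0.0719466       NA
```

The three rows reproduce the model's response classes: an excitable rest
that fires one spike, sustained oscillations of Ca²⁺ and potential with
period ≈ 19.5 η-units, and a switch to a high-calcium steady state.
Adding the hyperpolarisation current (`coupled_params(vCah = 0.9)`,
variant `"hyper"`) yields `multivibrator` at every current in the same
scan.

A thin command-line front end is installed with the package
(`system.file("cli/ciliadyn", package = "ciliadyn")`) with subcommands
`clamp`, `free`, `phase`, `scan`, `convert` and `preset`; trajectories are
written as fixed-header CSV with a YAML metadata sidecar.

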