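Package: ciliadyn
Title: Conductance-Based Modelling of Ciliary Calcium and Membrane-Potential
    Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled dynamics of intraciliary calcium
    concentration and ciliary membrane potential with voltage-dependent
    calcium, potassium, hyperpolarisation-activated and cilium-to-body
    conductances, calcium-dependent channel inhibition (direct and via a
    calcium-sensor protein), and saturating active transport. Provides
    voltage-clamp and free-membrane simulation protocols, spike metrics,
    nullcline and fixed-point analysis with linear stability, limit-cycle
    detection, and classification of the dynamic regime (single spike,
    sustained oscillation, switch, monostable multivibrator) as a function
    of the applied inward current. All computation is performed in the
    model's non-dimensional variables, with converters between millivolts /
    micromolar and the non-dimensional potential and calcium scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
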