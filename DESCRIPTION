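Package: hvgate
Title: Voltage-Clamp Gating Analysis of Two-Conductance Proton Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell voltage-clamp recordings of
    voltage-gated proton conductances: Nernstian reversal-potential
    utilities, a Hodgkin-Huxley-style two-conductance (plus ohmic leak)
    sweep simulator for step protocols, tail-current mono-exponential
    extrapolation, conductance-voltage Boltzmann fitting with parameter
    constraints and shared-parameter joint fits, a first-derivative
    Gaussian midpoint (V_PEAK) estimator for truncated gating curves,
    gating-valence and pH-dependence analyses, and a two-conductance
    decomposition of U-shaped conductance-voltage relations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
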