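Package: cdc42rd
Title: Bulk-Surface Reaction-Diffusion Analysis of Budding-Yeast Cdc42 Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-conserving bulk-surface reaction-diffusion model of the Cdc42
    polarization machinery of Saccharomyces cerevisiae, with the GTPase cycle,
    Bem1-mediated mutual recruitment, explicit GAP-Cdc42 complex kinetics and
    effective Cdc42 self-recruitment. Provides homogeneous steady-state solvers
    under protein copy-number conservation, spherical-harmonic linear stability
    analysis (dispersion relations, stability diagrams, critical GAP thresholds),
    mutant and functional-submodule scenarios, log-uniform parameter-space
    sampling with phenotype viability filtering, and an axisymmetric nonlinear
    simulator of spontaneous and stimulus-induced polarization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
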