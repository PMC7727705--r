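Package: gpcrdyn
Title: Equilibrium Dynamics of Membrane Receptors from Solid-State NMR and
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the fast equilibrium dynamics of membrane
    proteins, modelled on the combined solid-state NMR / molecular dynamics
    workflow used for class A G-protein-coupled receptors. Implements static
    chemical-shift-anisotropy powder lineshape simulation and deconvolution,
    cross-polarization buildup fitting with the I-S model, simulation and
    fitting of DipShift dipolar dephasing under magic-angle spinning,
    conversion of order parameters to wobbling-in-a-cone amplitudes,
    per-residue C-H order parameters from coordinate trajectories, helix and
    loop axis fitting, P2 orientation autocorrelation analysis with fast/slow
    order-parameter decomposition and correlation times, and a seeded
    synthetic-data generator with analytically known ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
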