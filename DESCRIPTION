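Package: hydrashell
Title: Hydration-Shell Dynamics Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators for the structural and dynamical properties of protein
    hydration water from molecular dynamics trajectories: per-atom fluctuation
    (RMSF) and deviation (RMSD) with rigid-body superposition, solvent
    accessible surface area, multi-time-origin mean square displacement with
    Einstein-relation diffusion coefficients, radial distribution functions
    with first-peak statistics, dynamical-transition breakpoint detection,
    hydration-shell residence correlation with stretched-exponential fitting,
    water dipole reorientation autocorrelation, and geometric hydrogen-bond
    population dynamics (continuous lifetimes and intermittent relaxation
    times). Includes trajectory readers (PDB, GRO, DCD), periodic-boundary
    utilities, a configuration-driven analysis pipeline, and synthetic
    trajectory generators with known ground-truth dynamics for validating
    every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
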