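Package: hemoflow
Title: Pulsatile Hemodynamics and Wall Shear Stress Analysis for Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational hemodynamics for saccular intracranial
    aneurysms: parametric generation of idealized aneurysm-bearing vessel
    geometries, surface-mesh processing (smoothing, opening extension,
    morphometry), lattice-based tetrahedral meshing, an incompressible
    Newtonian finite-element Navier-Stokes solver (bubble-stabilized
    linear elements, BDF time stepping) for steady and pulsatile flow,
    wall shear stress derived indices (TAWSS, OSI, LSA, PWSS and their
    normalized and peak-systole variants), rupture-site region statistics,
    and the computational side of particle image velocimetry validation
    (pathline tracing, focal-depth banding, line-probe velocity profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    deSolve
LinkingTo:
    Rcpp,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    xml2
SystemRequirements: C++17
Config/testthat/edition: 3
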