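Package: chargebem
Title: Charge-Based Boundary Element Method with Adaptive Mesh Refinement
    for Bioelectric Forward Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-static bioelectric forward modeling for transcranial
    electrical stimulation (TES) and EEG using the charge-based boundary
    element method. The unknown is the induced surface charge density on
    tissue conductivity interfaces, solved from a second-kind Fredholm
    integral equation by matrix-free GMRES with a direct or treecode
    Coulomb-sum backend. Includes voltage (Dirichlet) and current (sponge)
    electrode formulations with a sectored block single-layer
    preconditioner, a residual-driven adaptive mesh refinement loop built
    on an area-scaled surrogate charge residual and a local plus nonlocal
    refinement criterion, a fully specified 5-layer concentric-sphere
    benchmark with deep-target point grids, and convergence diagnostics
    for electrode currents and deep-structure electric fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
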