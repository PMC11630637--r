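Package: adhesim
Title: Catch-Bond Cell Adhesion Simulation and Molecular Trajectory Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell two-dimensional finite-element model of
    integrin-mediated adhesion with catch-slip bond kinetics, coupling a
    neo-Hookean plane-stress disk under ramped actomyosin contraction to a
    mean-field bond-concentration field at every mesh node. Also provides the
    molecular-trajectory metrics used to characterise integrin-fibronectin
    engagement: fluctuation (equipartition) stiffness with block averaging,
    force-extension departure energy, geometric hydrogen-bond detection,
    radius of gyration, inertia-axis inter-domain angles, pairwise-Coulomb
    punctual stress, and nonparametric condition comparisons. Seeded synthetic
    generators supply every input with known ground truth so the full pipeline
    is testable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
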