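Package: protrusim
Title: Programmed Growth of Cell Clusters via Diffusible Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of two-dimensional cell clusters whose
    local growth rates are controlled by secreted diffusible chemicals.
    Regulatory circuits of growth inhibitors, growth activators,
    secretion regulators and growth-threshold regulators set a spatial
    growth field via steady-state reaction-diffusion (modified Helmholtz)
    equations; the cluster then expands as an incompressible fluid
    (Darcy flow) whose boundary advances with the computed normal
    velocity. Includes front-tracking boundary evolution with adaptive
    remeshing, a boundary-integral velocity solver, named regulatory
    schemes producing rods, cones and multiple protrusions, regeneration
    (cut) experiments, and protrusion morphometrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
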