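Package: spotfate
Title: Spatial Tumor Architecture, RNA-Velocity Fate Graphs, and Prognostic
    Signatures on Hexagonal Spot Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for spatially resolved analysis of tumor architecture on
    Visium-style hexagonal spot lattices: malignant spot calling from
    deconvolution and copy-number probability channels, tumor core /
    transitory / leading edge annotation, consensus differential expression
    across samples, gene-set scoring (control-bin module scores, signed
    composites, and rank-based single-sample scores), hexagonal
    neighborhood composition, steady-state RNA velocity with coarse-grained
    fate-transition state graphs, in-silico drug-target perturbation with
    drug-response association, and maximally selected survival cutpoints
    with proportional-hazards fits. Includes seeded generators for
    synthetic spatial samples, splicing kinetics, drug screens, and
    survival cohorts so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
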