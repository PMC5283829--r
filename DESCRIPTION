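Package: soilchip
Title: Spatial Competition Analysis for Biofilms in Soil-Mimicking
    Microfluidic Chambers
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spatial competition between
    matrix-producing and matrix-deficient bacteria growing in
    obstacle-containing (soil-mimicking) microfluidic chambers.
    Generates porous column layouts from cross-sections of perturbed
    close-packed sphere beds, tessellates chamber images into triangular
    sampling regions with column centers as nodes, scores per-region
    biofilm occupancy and local flow from fluorescent bead streak
    images, computes area-normalized strain occurrence in blocked
    versus open flow regions with pooled two-sample t-tests and
    Bonferroni correction, and characterizes frequency-dependent
    selection from competition assays. A synthetic-data module renders
    two-channel chamber scenes, bead-streak stacks, competition tables
    and logistic growth curves with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    deldir,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
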