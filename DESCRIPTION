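Package: svtomo
Title: Subtomogram Averaging and Symmetry Analysis of Docked Synaptic Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the supra-molecular organization of the
    exocytic release machinery under docked synaptic-like vesicles in
    cryo-electron tomograms. Provides a synthetic phantom generator for
    docked-vesicle subtomograms (missing wedge, additive noise, configurable
    interface protein assemblies including a disorganized mutant mode), MRC
    volume and particle-table input/output, spherical-template vesicle
    detection with sphere-assumption diameter estimation and a docked-vesicle
    clearance criterion, a wedge-constrained alignment and multivariate
    statistical analysis / hierarchical ascendant classification pipeline,
    rotational-symmetry detection with permutation significance, Cn map
    averaging, interface ring-geometry measurement, sigma-threshold component
    analysis, and a mechanically coupled SNAREpin release-time model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
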