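Package: lignoporo
Title: Physico-Chemical Characterization of Lignocellulosic Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipelines for laboratory characterization of wood and
    other lignocellulosic biomass: conversion of dynamic vapour sorption
    (DVS) kinetic traces into equilibrium isotherms and Park-model fits with
    the mean relative deviation (MRD) goodness-of-fit modulus; inversion of
    stepwise-isothermal DSC thermoporosimetry thermograms into
    Gibbs-Thomson pore-size distributions; mask-based quantification of
    immunofluorescence in two-channel z-stacks; green-density and
    percent-change calculators; and the assumption-gated group-comparison
    workflow (Shapiro/Bartlett gate, ANOVA + Tukey HSD or Kruskal-Wallis +
    rank-based pairwise tests, compact letter display). A synthetic-data
    module simulates every instrument trace with known ground truth so each
    pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite,
    tiff,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
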