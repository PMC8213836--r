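Package: leverlink
Title: Simulation and Analysis of Multivalent Receptor Crosslinking on
    Biosensor Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how multivalent antibody-like binders interlink
    surface-tethered receptors. Implements a stochastic-geometry Monte
    Carlo model of DNA-nanolever surfaces (hexagonal tessellation with
    density-controlled lever placement) and a sequential saturation-binding
    rule that yields the fraction of interlinked levers as a function of
    binder reach and surface density; exponential association/dissociation
    curve fitting for fluorescence-proximity binding traces (k_on, k_off,
    K_D with mono-/biphasic model selection); and a density-clustering
    estimator of the immobile receptor fraction from single-molecule
    localization data, with synthetic-data generators for all three
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
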