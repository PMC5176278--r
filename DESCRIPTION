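Package: mirtumor
Title: Exosomal microRNA-Driven Model of Early Lung Cancer Invasion and
    Proliferation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for a mechanistic model of early non-small-cell lung
    cancer driven by the exosomal microRNAs miR-21/205 and miR-155. Couples
    an intracellular EGFR/MAPK/AKT/PTEN signalling network to exosome and
    microRNA reaction-diffusion, a one-dimensional tumor-front invasion model
    with a nonlinear directed-migration flux, and a spherically symmetric
    free-boundary proliferation model solved on a moving mesh. Includes exact
    derivation of all kinetic parameters from literature constants via unit
    conversions and steady-state inversion, built-in mutation, anti-miR and
    chemotherapy scenarios with efficacy metrics, and Latin hypercube /
    partial rank correlation global sensitivity analysis of the tumor radius.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
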