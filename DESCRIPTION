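Package: mase
Title: Dissociation Kinetics of Protein Complexes from Metabolically
    Labeled Subunit Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and estimators for subunit-exchange kinetics of
    heterodimeric protein complexes measured by metabolic stable-isotope
    labeling and affinity purification (the MASE design). Provides the
    closed-form exchange progress curve R(t) = tanh(k_off * t / 2) linking
    the hybrid-to-original complex abundance ratio to the dissociation rate
    constant, a full eight-species mass-action ODE simulator of lysate
    mixing and exchange, an exact event-driven stochastic simulator for
    small copy numbers, a synthetic-measurement generator emulating
    peptide-level isotope-ratio quantification noise, and a nonlinear
    least-squares estimator of k_off with residual-bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
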