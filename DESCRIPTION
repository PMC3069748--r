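Package: phasekit
Title: Likelihood-Based Experimental Phasing for Anomalous Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for macromolecular experimental phasing
    from anomalous and isomorphous difference data: heavy-atom amplitude
    (|FA|) estimation from Friedel pairs, anomalous-difference Patterson
    substructure search with early-termination rules, likelihood-based
    substructure phasing producing Hendrickson-Lattman coefficients and
    figures of merit, Luzzati error-parameter refinement with a
    substructure-completeness check, solvent-flattening density
    modification with correlation-aware phase combination and
    cross-validated error estimation, and enantiomorph (hand)
    determination.  A synthetic-crystal simulator provides ground truth
    (true phases, heavy-atom structure factors and site coordinates) for
    every stage, and a pipeline driver orchestrates the steps for SAD,
    MAD and SIRAS experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
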