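Package: netattack
Title: Targeted and Random Attack Simulation on Psychopathological Symptom Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the vulnerability of psychopathological symptom
    networks to symptom deactivation. Estimates weighted networks from raw data
    (regularized partial-correlation models for continuous data, nodewise
    logistic Ising fits for binary data, both with extended-BIC model
    selection), ranks symptoms by degree, strength, modular overlap and modular
    bridgeness, simulates sequential node-removal attacks under targeted and
    random regimes while tracking connectivity, components and average path
    length, reduces attack trajectories to impact-magnitude and attack-extent
    outcomes, and compares attack conditions with robust trimmed-mean
    dependent-samples bootstrap-t tests. Includes synthetic-network generators
    with planted modular structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    glmnet,
    MASS,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
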