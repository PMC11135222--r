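Package: CDRknn
Title: Sequence-Based Antibody-Antigen Binding Classification from CDR
    Distances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts antibody-antigen binding from sequence alone using
    generalized Levenshtein distances over the six complementarity-determining
    regions (CDRs), with identity or BLOSUM62-derived substitution costs.
    Provides a distance-weighted K-nearest-neighbor classifier with a fixed
    cross-antigen penalty, a 13-feature per-feature-vote ensemble combining
    the CDR string distance with per-CDR hydrophilicity and isoelectric
    point, per-antigen leave-one-out cross-validation, conversion of docking
    interface scores into binding labels, per-CDR physicochemical feature
    calculators (net charge, isoelectric point, average hydrophilicity), a
    pair-table CSV schema with validation, and a synthetic pair-table
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
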