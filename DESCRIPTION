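Package: taxonvet
Title: Quality Assessment and Resolution of Taxon Names in Darwin Core
    Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the scientific names attached to digitized
    biocollections records. Assembles candidate name strings from verbatim
    Darwin Core taxon fields, detects and classifies four issue types
    (misspellings, format errors, Darwin Core conceptual errors, synonymy),
    resolves names to valid canonical forms against a local pluggable
    taxonomic authority using exact and Damerau-Levenshtein fuzzy matching,
    links assessments back to occurrence records, summarizes issue
    prevalence, and models issue drivers with logistic regression including
    exhaustive AIC selection over two-way interactions. Ships a synthetic
    data generator with known truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
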