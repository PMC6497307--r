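Package: bofkit
Title: Data-Driven Biomass Objective Functions for Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biomass objective functions (BOFs) for constraint-based
    genome-scale metabolic models from experimental data in three steps:
    stoichiometric coefficients for the major macromolecules (DNA, RNA,
    protein, lipids) and ATP maintenance costs from omic data and growth
    measurements; coenzyme and inorganic-ion identification with
    soluble-pool coefficients; and a genetic algorithm over gene
    essentiality data that discovers species-specific metabolic end goals,
    interpreted by network-distance clustering. Includes flux balance
    analysis and single-gene-deletion services over SBML-FBC and BiGG-style
    JSON models, evaluation metrics for comparing BOFs (metabolite overlap,
    Levenshtein distance, growth rate, Matthews correlation coefficient),
    and synthetic fixture generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
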