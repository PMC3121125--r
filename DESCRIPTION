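Package: cyclenet
Title: Integrative Prediction of Cell Cycle-Related Genes from Genetic
    Interaction and Co-Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates quantitative genetic-interaction screens (E-MAP
    S-scores), time-lagged co-expression from cell-cycle time-course
    microarrays, transcription-factor binding (chip-chip) data and
    kinase-substrate lists to nominate potential cell cycle-related genes
    in budding yeast. Provides co-functionality enrichment surfaces over
    (S-score, correlation) thresholds, extraction of a potential
    cell-cycle gene set from a significance region, hypergeometric
    enrichment testing with Bonferroni correction, rank-product
    prioritization of periodically expressed and target-enriched
    transcription factors, coverage-based TF selection, indirect
    regulatory connectivity analysis and binding-profile clustering,
    together with a fully synthetic data generator with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
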