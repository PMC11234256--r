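Package: apmsenrich
Title: Comparative AP-MS Interactome Enrichment with Adaptive Two-Stage FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparative analysis of affinity-purification
    mass-spectrometry (AP-MS) interactomics experiments quantified by
    isobaric (TMT) multiplexing: filtering of nonspecific binders against
    no-transfection negative controls, bait normalization, per-protein fold
    enrichment between bait variants, homoscedastic and Welch t-tests, and
    the adaptive two-stage step-up false discovery rate procedure of
    Benjamini, Krieger and Yekutieli with search-based q-values.  Includes
    blinded multi-rater retention-scoring statistics for tissue imaging
    data, and a synthetic-data generator with ground-truth labels so the
    full discovery pipeline can be validated by simulation, including
    empirical FDR benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
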