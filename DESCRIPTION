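Package: sigselect
Title: Stable Gene-Expression Signature Discovery by Ensemble Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A battery of feature-selection search strategies (recursive
    feature elimination with mutual-information coefficients, minimum
    redundancy maximum relevance, univariate forward selection, a genetic
    algorithm) and evaluation criteria (wrapper cross-validation of
    classifiers, distance-matrix class separation, supervised clustering
    with Dunn or figure-of-merit choice) for discovering gene-expression
    signatures from log2-ratio microarray-style data.  Selection is wrapped
    in external k-fold resampling with Hamming-distance stability and
    frequency-based ensemble aggregation; signatures are characterized by
    hypergeometric pathway enrichment, hierarchical clustering with
    multiscale-bootstrap (AU/BP) cluster support, and Kaplan-Meier /
    log-rank survival validation.  A seeded synthetic-data generator
    emulating staged disease progression, correlated gene blocks, enriched
    pathways and latent survival subtypes makes the whole pipeline testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    cluster,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
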