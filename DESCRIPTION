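Package: topothought
Title: Semantic Speed, Volume, and Circuitousness of Document Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Represents a document as an ordered trajectory of chunk
    embeddings in a word-vector space and measures the topography of that
    trajectory: semantic speed (mean Euclidean displacement between
    consecutive chunks), semantic volume (minimum-volume enclosing
    ellipsoid of the chunk points, computed in their affine hull),
    minimum required speed (shortest path through the same points with the
    original endpoints fixed, an open traveling-salesperson optimum), and
    circuitousness (observed speed over minimum required speed). Provides
    corpus-level orchestration with log transformation, corpus
    standardization and per-author averaging, standardized least-squares
    and ridge association models with covariates and fixed effects, and a
    deterministic synthetic-data module (hash-based embedding stores,
    planted trajectories, simulated corpora with planted effects) so every
    stage can be exercised without external language resources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
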