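Package: glycontext
Title: Contextual Similarity Assessment for Sparse Glycopeptide
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quality-aware comparison of glycopeptide abundance matrices
    from low-replicate, high-missingness LC-MS/MS experiments. Implements a
    presence- and distance-weighted Tanimoto similarity over standardized
    log abundances, bootstrap resampling of replicates into Internal, Test
    and Null similarity distributions, density-overlap false positive and
    false negative rates, an overlap-weighted Internal Confidence score,
    replicate outlier detection by peak membership, and per-glycopeptide
    contribution ranking with quality failure causes. Includes a seeded
    synthetic-data generator for sparse glycopeptide abundance scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
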