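Package: mirdap
Title: miRNA-Disease Association Prediction by Similarity-Based Neighbor Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate miRNA-disease associations with a k-nearest-neighbour
    collaborative recommender over heterogeneous biological networks. miRNA
    similarity is computed from shared target mRNAs with an information-entropy
    kernel and boosted by miRNA family co-membership; disease similarity combines
    a gene-interaction entropy kernel with MeSH-tree semantic similarity; a
    genomic-cluster vote (miRNAs within 20 kb) augments the miRNA-space score.
    Includes leave-one-out cross-validation with pooled rank-threshold ROC
    curves, cold-start (isolated disease / isolated miRNA) evaluation, a
    parameter grid sweep, and a seeded synthetic-data generator with planted
    block structure so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
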