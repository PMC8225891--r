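Package: simbins
Title: Information-Theoretic Similarity Fusion for Link Prediction in
    Multiplex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Link prediction on one layer of a multiplex network using
    structural information from an auxiliary layer. Node pairs are scored by
    fusing a min-max normalized base similarity (common neighbours, resource
    allocation, average commute time, or local path index) with empirical
    intra-layer and trans-layer connection probabilities estimated over
    equal-depth similarity bins, combined with a probabilistic OR and
    expressed in bits. Includes single-layer and additive baselines,
    relevance-weighted comparator scorers, sampled AUC and precision
    evaluation with repeated train/test splits, a correlated duplex network
    generator, and readers and writers for multiplex edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
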