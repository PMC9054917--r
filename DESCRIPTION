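Package: mlmr
Title: Graph-Based Semi-Supervised Multi-Label Learning with Manifold
    Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised multi-label classification by manifold
    regularization on a similarity graph. Builds Gaussian-kernel affinity
    graphs with epsilon-neighborhood, k-nearest-neighbor or b-matching
    sparsification, fits a multi-label Laplacian regularized least squares
    model in closed form, and supports a reliance-weighted kernel variant
    that trusts labeled training instances more than unlabeled ones when
    predicting out-of-sample. Includes multi-label ranking and F1 metrics,
    a Friedman rank test with post-hoc critical-difference comparisons, a
    repeated-resampling evaluation protocol over labeling rates, and a
    cluster-structured synthetic multi-label data generator in the shape of
    gene function annotation benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2,
    foreign
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
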