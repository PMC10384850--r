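Package: qsardr
Title: Benchmarking Dimensionality Reduction for Deep-Learning QSAR
    Models of Mutagenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable benchmark of six dimensionality-reduction
    techniques (PCA, kernel PCA with RBF and sigmoid kernels, FastICA,
    autoencoders, locally linear embedding and isomap) for deep-learning
    QSAR classification of Ames mutagenicity. Feature engineering builds
    an all-against-all Tanimoto similarity matrix whose rows are feature
    vectors; an imbalanced dataset is stratified into perfectly balanced
    cross-validation folds plus a permanent majority-class testing pool;
    each reducer is fitted on training folds with genuine out-of-sample
    projection, optimised by a two-hyperparameter grid search at a fixed
    100-dimensional reduction, and compared across a dimensionality sweep
    with a fixed multi-layer-perceptron classifier and prevalence-weighted
    metrics. Applicability-domain and chemical-space diagnostics analyse
    performance in XLogP/molecular-weight space. A seeded synthetic-data
    generator emulates the class imbalance, block-structured fingerprints
    and radially exponential physicochemical geometry the analysis
    assumes, so every stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
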