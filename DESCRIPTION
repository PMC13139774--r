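Package: mscontab
Title: Multi-Scale Contrastive TabNet Embeddings for Cancer Cohort Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised cohort-level clustering of cancer types from somatic
    coding single-nucleotide substitution tables. Builds two complementary
    mutation-signature views per cohort (top-25-gene x 12-substitution counts,
    flattened to 300 dimensions, and 24-chromosome x 12-substitution
    length-normalized rates, flattened to 288), encodes each view with a
    sparsemax-attentive TabNet encoder, aligns the views with an NT-Xent
    contrastive objective, and clusters the fused 64-dimensional embeddings.
    Includes internal cluster-validity metrics, baseline embedding methods
    (NMF, Ward hierarchical, autoencoder, SimCLR-style MLP, DeepCluster),
    an ablation grid, a synthetic mutation-cohort generator with planted
    cluster structure, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
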