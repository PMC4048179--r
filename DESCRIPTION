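Package: structmap
Title: Structured Association Mapping of Genome, Transcriptome and Phenome Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sparse structured multivariate and multi-task regression for
    association mapping between genotypes, gene-expression traits and clinical
    phenotypes. Implements the lasso, group lasso, graph-guided fused lasso
    (GFlasso), tree-guided group lasso (TreeLasso), adaptive multi-task lasso,
    multi-population group lasso and structured input-output regression, with
    coordinate-descent and smoothing proximal-gradient (FISTA) optimizers and
    cross-validated model selection. Also provides trait-network construction
    (correlation, soft thresholding, graphical lasso), hierarchical trait
    trees, gene-module discovery with hypergeometric enrichment, a two-stage
    genome-transcriptome-phenome pipeline with cis/trans classification and
    eQTL hotspot detection, single-marker association tests with
    population-stratified analyses, and a synthetic-data generator with
    linkage-disequilibrium blocks, co-expression modules, trans hotspots and
    population structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    yaml,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
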