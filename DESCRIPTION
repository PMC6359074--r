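Package: metshift
Title: Condition-Contrast Analysis of Untargeted Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for contrasting untargeted-metabolomics feature tables
    across dietary conditions and phenotype classes: minimum-value imputation
    and log transformation, random-forest discrimination with out-of-bag
    tuning of mtry and permutation variable importance, Ward clustering of
    top metabolites, condition-specific Gaussian graphical model inference by
    nodewise-Lasso neighborhood selection with a penalized (K, dmax) graph
    criterion, and network-difference statistics (edge symmetric difference,
    edge-count-matched Pearson correlation baseline, three-way edge
    conservation). Includes a synthetic metabolite-table generator with
    ground-truth condition graphs, planted diet differentiators and a
    phenotype-linked correlated block for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    randomForest,
    igraph,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
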