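Package: phenoRBM
Title: Conditional Restricted Boltzmann Machines for Multi-Phenotype
    Drug-Disease Association Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint prediction of the three clinical phenotype types of
    drug-disease associations (indication, side effect, contraindication)
    from a binary drugs x diseases x 3 association tensor. A conditional
    restricted Boltzmann machine with per-drug visible layers and shared
    weights is trained by contrastive divergence and scores all three
    phenotype types for every drug-disease pair simultaneously. Includes
    the per-type down-sampling procedure that balances association counts,
    drug- and disease-based k-nearest-neighbour and tree-ensemble
    baselines, tenfold and leave-one-class-out cross-validation with
    ROC/PR metrics and a degree-destroying permutation null, and a
    synthetic tensor generator with planted latent structure and
    cross-type dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, MachineLearning, Pharmacogenomics, Classification
RoxygenNote: 7.3.3
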