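Package: ProfilePPI
Title: Protein-Protein Interaction Prediction from Evolutionary Sequence Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interactions from evolutionary
    information in protein sequences. Position-specific scoring matrices
    (PSSMs) are compressed to fixed 20x20 profile matrices, a denoising
    autoencoder learns a low-dimensional representation per protein, and a
    gradient-boosted tree classifier scores protein pairs. Includes a
    PSI-BLAST ASCII PSSM reader/writer, a histogram-of-oriented-gradients
    baseline extractor, an ordered target statistic encoder, a stratified
    cross-validation harness with ACC/PE/SN/MCC/AUC reporting, and a
    synthetic planted-signal benchmark generator so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    xgboost,
    e1071,
    MASS,
    rpart,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, NetworkInference, Classification, FeatureExtraction
RoxygenNote: 7.3.3
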