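Package: modin
Title: Multi-Omics Drug-Cell Interaction Network for Drug Sensitivity
    Prediction and Metabolic Subtyping
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts log-IC50 drug sensitivity from pathway-structured
    multi-omics profiles (copy number, mRNA expression, DNA methylation)
    and drug structural fingerprints.  Cell lines are encoded as 3-channel
    pathway-by-gene feature grids fed to a stacked convolutional network,
    drugs as 2048-bit hashed circular fingerprints passed through a
    multilayer perceptron, and the two representations interact through
    multi-head cross-modal attention that regresses LN_IC50.  Also
    provides Monti-style consensus clustering of pathway enrichment
    scores for metabolic subtype discovery with CDF/delta-area model
    selection, subtype-versus-subtype drug-sensitivity comparison
    (Kolmogorov-Smirnov and Welch t tests), an omics-combination ablation
    harness, and a fully seeded synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'drugs.R'
    'nn-layers.R'
    'nn-model.R'
    'encode.R'
    'methods.R'
    'nn-optim.R'
    'omics.R'
    'simulate.R'
    'subtype.R'
    'train.R'
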