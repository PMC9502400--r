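Package: fpscreen
Title: Fingerprint-Based Machine-Learning Virtual Screening for Kinase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A ligand-based virtual-screening toolkit for binary
    activity classification of small molecules against a protein target,
    developed around Cdk5 inhibitor discovery. Provides bioactivity
    data curation (structure standardization, replicate aggregation with
    outlier discard, potency thresholds at 1 and 5 micromolar),
    six binary molecular fingerprint families including 2048-bit Morgan
    circular fingerprints and 166-key MACCS, Tanimoto-kernel support
    vector machines alongside random forest, nearest-neighbour and
    multi-layer perceptron classifiers with MCC-scored grid search and
    repeated random-split cross-validation, probability-score consensus
    classification, precision-oriented threshold analysis, library
    screening with maximum-score retention and leader-style diversity
    clustering, and a synthetic ChEMBL-like benchmark generator with a
    hidden substructure-activity rule for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    kernlab,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
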