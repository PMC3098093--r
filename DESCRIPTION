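Package: openzfp
Title: Activity Prediction and Target-Space Analysis for OPEN-Engineered
    Zinc Finger Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which 9-bp DNA sites are worth attempting
    with Oligomerized Pool ENgineering (OPEN) of three-finger C2H2 zinc
    finger arrays. Implements a categorical naive Bayes classifier over
    three target-site encodings (sequence identity, base counts,
    positional base counts), a balanced-resampling RBF support vector
    machine protocol, leave-one-out cross-validation with the standard
    confusion-matrix metrics and ROC/AUC, a 0-9 confidence score derived
    from the classifier posterior, base-composition analytics for labeled
    site collections, enumeration of the OPEN-targetable 9-mer space with
    dam/dcm methylation exclusion, scanning of DNA sequences for paired
    zinc finger nuclease (ZFN) half-sites around a 5-7 bp spacer, and a
    synthetic labeled-site generator with a logistic thymine-penalty
    activity model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    readr,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
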