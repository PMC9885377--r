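Package: mlpitfalls
Title: Synthetic Experiments Quantifying Methodological Pitfalls in
    Medical-Imaging Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired experiment harness and synthetic-data generators for
    quantifying three methodological pitfalls in machine-learning model
    development for medical imaging: violations of the independence
    assumption between training and test data (oversampling, data
    augmentation, or feature selection applied before data splitting, and
    row-level splitting of per-patient data), misleading performance
    indicators and baselines (accuracy under class imbalance; Dice and IoU
    of a trivial Hounsfield-threshold internal-air lung proxy), and batch
    effects that confound class labels with acquisition source. Includes
    group-coherent splitting utilities, a leakage auditor, classification
    and segmentation metrics with a tie- and continuity-corrected Wilcoxon
    rank-sum comparison, a whole-slide-style patch extractor, and
    command-style wrappers that serialize results to CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
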