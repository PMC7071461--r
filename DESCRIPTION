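Package: eegmoments
Title: Welch Band-Moment Feature Extraction and Subject-Level
    Classification of Resting EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for two-class classification of
    resting-state multichannel EEG epochs. Recordings are bandpass- and
    notch-filtered, segmented into nonoverlapping 5-second epochs, and
    summarised per channel by the four statistical moments (mean, standard
    deviation, skewness, kurtosis) of the Welch power spectral density
    within the conventional delta, theta, alpha, beta and whole-band
    (1-32 Hz) rhythms. The resulting epoch-by-feature tables feed RBF-SVM,
    LDA and Gaussian naive Bayes classifiers evaluated under subject-level
    random-split and leave-one-subject-out validation with confusion-matrix
    metrics and ROC/AUC summaries. A synthetic cohort generator (band-limited
    Gaussian noise on a 1/f background with per-subject power jitter)
    provides fully reproducible labelled cohorts for calibration and
    testing. Readers and writers for ASCII/CSV matrices and EDF files are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    MASS,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
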