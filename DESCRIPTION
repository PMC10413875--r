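Package: ppgbp
Title: Blood-Pressure Variation Detection from Photoplethysmography Under
    Hypovolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting blood-pressure variation from the morphology
    of the photoplethysmography (PPG) pulse wave recorded under a constant
    external cuff pressure (the volume-compensation principle). Provides a
    synthetic PPG/blood-pressure/cuff-pressure signal generator emulating
    hemorrhagic hypovolemia, pulse preprocessing (band-pass filtering,
    trough-to-trough cycle segmentation, amplitude and length normalization,
    template and moving-average sample waveforms), constant cuff-pressure
    estimation from envelope peak-to-peak amplitude, three morphological
    features (rising-edge area, one-third-peak area difference, template
    cross-correlation difference), delta-BP labeling with class balancing,
    single-feature threshold classifiers selected by Youden's index,
    tree-based multi-feature classifiers, ten-fold cross-validation with six
    evaluation metrics, and Bland-Altman / British Hypertension Society
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    zoo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
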