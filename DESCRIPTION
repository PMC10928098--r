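Package: bilphantom
Title: Synthetic Tissue-Phantom Imaging and Machine-Learning Analysis for
    Smartphone Bilirubin Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study smartphone-image colorimetric estimation of
    bilirubin on PDMS-TiO2 tissue phantoms. Renders calibrated synthetic
    phantom scenes whose channel-versus-concentration statistics follow
    printed experimental relationships, corrects white balance with four
    colour-constancy estimators scored by angular error, converts device
    RGB to CMYK, CIELAB, HSV, YCbCr and CIELUV feature spaces, extracts
    region-of-interest features, reproduces the parametric sensitivity
    analysis (per-condition linear fits, slope comparisons, Kruskal-Wallis
    with Dunn post-hoc, paired Wilcoxon), and trains five classification
    and regression models with grid search, repeated cross-validation,
    ROC/AUC and permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    optparse
Config/testthat/edition: 3
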