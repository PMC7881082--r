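Package: ictalEEG
Title: Seizure Detection from Multichannel Scalp EEG by Variance-Based
    Channel Selection and Statistical Feature Classification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated seizure/normal classification of
    multichannel scalp EEG. Records are cut into fixed-length epochs,
    the highest-variance channels of each epoch are selected, eleven
    statistical and spectral features are extracted per channel and
    averaged across channels, and seven standard classifiers are trained
    and evaluated with stratified k-fold cross-validation under random
    and continuous testing protocols. Includes EDF and CSV signal I/O,
    a full confusion-matrix metric suite on the percent scale, an
    outlier filter for training tables, and a seeded synthetic EEG
    generator that emulates 23-channel 256 Hz recordings with ictal
    spike-wave bursts for testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    MASS,
    class,
    rpart,
    randomForest,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, Epilepsy, FeatureExtraction, Preprocessing
RoxygenNote: 7.3.3
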