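Package: msfallrisk
Title: Free-Living Gait Analysis and Fall-Risk Classification for Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing fall risk in persons with multiple
    sclerosis from dual-site (chest and right-thigh) wearable accelerometry.
    Covers activity classification of 4-second windows into gait/non-gait and
    assembly of walking bouts, stride event detection (foot contact, foot off)
    via cadence estimation from the power spectral density and a narrow-band
    filter bank, per-bout gait parameters (temporal parameters, stride-time
    variability, duty factor, RMS anterior-posterior acceleration,
    medial-lateral frequency dispersion, thigh/chest sample-entropy ratio,
    largest Lyapunov exponents), walking-bout duration stratification with
    Wilcoxon comparison suites, and leave-one-subject-out fall-risk
    classification with feature-based models and recurrent sequence models.
    Includes a synthetic dual-sensor accelerometry generator with full ground
    truth so every stage is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    e1071,
    rpart,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
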