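Package: ccepml
Title: Predicting Postoperative Speech Deterioration from Intraoperative
    Cortico-Cortical Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for analysing intraoperative
    cortico-cortical evoked potentials (CCEP) recorded between cortical
    speech areas during awake tumour resection, and for predicting
    postoperative speech deterioration from them. Provides EDF epoch and
    cohort-manifest input/output, waveform reduction (bin averaging,
    trailing moving-average smoothing, stimulus-artifact trimming,
    highest-amplitude channel selection), descriptive feature extraction
    (channel amplitude summaries, constrained local extrema with
    latencies, two missing-value imputation schemes, an augmented
    Dickey-Fuller stationarity feature, min-max normalisation), and a
    repeated-resampling classification experiment comparing record-level
    and patient-grouped train/test splitting across several classifier
    families. A synthetic cohort generator with known ground truth stands
    in for clinical recordings and supports recovery and calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
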