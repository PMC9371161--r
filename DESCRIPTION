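Package: apneamer
Title: Obstructive Sleep Apnea Detection from Polysomnography with a
    Multi-Error-Reduction Stacked Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of obstructive sleep apnea events from
    multi-channel polysomnography (oxygen saturation, airflow, thoracic and
    abdominal effort, ECG). Provides channel-specific preprocessing
    (artifact removal, zero-phase Butterworth filtering, Pan-Tompkins
    R-peak detection, RR correction, ECG-derived respiration), a 66-feature
    multi-domain extraction battery (time-domain statistics, Lempel-Ziv
    complexity, Poincare SD1, Yule-Walker and Welch spectral features,
    wavelet entropies, kernel PCA of QRS morphology), a two-stage feature
    selection combining per-patient significance counting with SVM
    hill-climbing, and a multi-error-reduction stacked classifier (four
    gradient-boosting base learners with a neural-network meta-learner).
    A seeded synthetic polysomnography generator with ground-truth
    annotations makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    xgboost,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC
Config/testthat/edition: 3
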