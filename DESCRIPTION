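Package: ActiCAR
Title: Circadian Activity Rhythm Analysis for Wrist Actigraphy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing circadian activity rhythms (CAR) in
    epoch-level wrist-actigraphy METs recordings from rehabilitation
    inpatients. Implements two-component (24-h + 12-h) synthetic periodic
    regression with closed-form least squares, extraction of the six CAR
    parameters (mesor, maximum, minimum, range, maximum/minimum phase time),
    an R-squared period scan over 720 candidate cycles, Cole-Kripke
    sleep/wake scoring with main-sleep-bout detection and nightly sleep
    metrics, METs-based sedentary/light/moderate activity classification,
    and a cohort statistics layer (Welch/Mann-Whitney comparisons,
    Pearson/Spearman correlations, single and multiple regression with
    Durbin-Watson and variance inflation diagnostics). A calibrated
    synthetic-cohort generator emulates ward-scheduled inpatient recordings
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), lmtest, car, withr
Config/testthat/edition: 3
biocViews: CircadianRhythms, TimeCourse, Regression, Epidemiology
RoxygenNote: 7.3.3
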