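Package: acgtools
Title: Simulation and Analysis of Multifrequency Transcranial Ultrasound
    (Acoustocerebrography) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for acoustocerebrography (ACG), a multifrequency
    transcranial ultrasound technique that records time-of-flight and
    attenuation curves at several carrier frequencies. Provides a
    synthetic septic/control cohort generator built on a toy dispersive
    propagation model, the PCA-based "dimensionality" statistic that
    scores asynchronicity of frequency channels, a large deterministic
    per-patient-day feature table, genetic-algorithm feature selection
    with first-principal-component correlation fitness, support-vector
    machine classification with stratified cross-validation and ROC
    analysis, nonparametric group-comparison and correlation reports,
    and a seeded end-to-end pipeline with cached stage artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
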