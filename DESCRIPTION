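Package: erdnf
Title: Motor-Imagery Neurofeedback Simulation and Event-Related
    Desynchronization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-channel sensorimotor EEG with a controllable,
    lateralized event-related desynchronization (ERD) and re-implements a
    complete motor-imagery neurofeedback analysis chain: FIR/Butterworth
    filtering, epoching, channel quality control and artifact rejection,
    Common Spatial Patterns (CSP) fitting under a contralateral/ipsilateral
    application convention, log band-power features with cross-validated
    linear discriminant classifiers and quartile border calibration for
    feedback mapping, ERD quantification relative to a pre-stimulus
    reference, and the accompanying statistical battery (paired and pooled
    independent t-tests with Cohen's d, mixed repeated-measures ANOVA with
    Mauchly's sphericity test and Greenhouse-Geisser correction,
    Bonferroni-Holm adjustment, Shapiro-Wilk and Levene checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
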