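Package: petscreen
Title: Plasma Biomarker Pre-Screening Simulation for Amyloid PET Trial Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating plasma-biomarker pre-screening strategies in
    secondary prevention trials of Alzheimer's disease. Fits a logistic model
    predicting amyloid PET positivity from plasma amyloid-beta 42/40, APOE e4
    carrier status and age; sweeps relative- and absolute-risk invitation
    thresholds to estimate PET-positive yield and the number of plasma and PET
    tests needed to recruit a fixed number of PET-positive participants; and
    converts test counts into recruitment-cost savings across PET-to-plasma
    cost ratios, with bootstrap confidence intervals and p-values throughout.
    Includes a calibrated synthetic-cohort generator emulating a cognitively
    unimpaired memory-clinic population, and a mixture-model derivation of the
    PET SUVR positivity cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    grDevices,
    grid,
    stats,
    utils,
    tools,
    jsonlite,
    mclust,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
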