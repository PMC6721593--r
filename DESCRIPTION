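Package: adipoct
Title: Peritumoral Breast Adipose Tissue CT Attenuation and Recurrence-Free
    Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the CT attenuation of tumor-adjacent and contralateral
    breast adipose tissue from paired PET/CT volumes and evaluates its
    prognostic value for recurrence-free survival. Provides a synthetic
    breast PET/CT phantom generator with programmable peritumoral
    fat-attenuation shifts, a survival-cohort simulator driven by a
    proportional-hazards model, spheroid volume-of-interest construction with
    contralateral mirroring, fat-window Hounsfield-unit measurements, SUVmax
    and metabolic tumor volume, and the accompanying statistical battery:
    Lin's concordance correlation, paired and two-sample comparisons,
    Kruskal-Wallis with Conover-Iman post-hoc tests, Cox regression,
    Kaplan-Meier curves, Youden-index ROC cutoffs, and stratified recurrence
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
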