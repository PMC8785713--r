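Package: taigrade
Title: MRI-Based Traumatic Axonal Injury Grading and Outcome Prognostication in TBI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the prognostic value of traumatic axonal injury (TAI)
    detected on MRI in critically ill traumatic brain injury (TBI) patients. Implements
    four rule-based TAI grading systems (Adams, Firsching, Abu Hamdeh, and the Stockholm
    MRI grading system), a synthetic-cohort simulator calibrated to published cohort
    tables, genetic-algorithm feature selection with a desirability objective and
    random-forest internal validation, and a logistic-regression model-comparison
    battery (AUC, Nagelkerke pseudo-R2, AIC, DeLong and likelihood-ratio tests,
    Cochran-Armitage trend test), plus lightweight chained-equation imputation and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
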