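Package: sustainr
Title: Subtype and Stage Inference for Z-Score Event-Based Disease Progression Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multi-subtype z-score event-based disease progression models
    to cross-sectional regional brain volumes and transfers them to independent
    cohorts. Biomarker trajectories are modelled as piecewise-linear successions
    of control-referenced z-score events; the number of subtypes is selected by
    a cross-validation information criterion and subjects receive maximum-
    likelihood subtype and stage assignments. Includes the full preprocessing
    chain (covariate adjustment by multiple linear regression, z-scoring
    against amyloid-negative controls, CSF rescaling), a seeded synthetic
    cohort generator for end-to-end testing, and a validation battery
    (visual-rating atrophy subtypes, longitudinal subtype consistency,
    stage-cognition regression, conversion classification with ROC and DeLong
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
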