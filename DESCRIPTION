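Package: ogttpheno
Title: Metabolic Subphenotyping from OGTT and CGM Glucose Curve Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies four metabolic subphenotypes of dysglycaemia (muscle
    insulin resistance, beta-cell dysfunction, impaired incretin effect and
    hepatic insulin resistance) from oral glucose-tolerance test (OGTT) and
    isoglycaemic intravenous glucose infusion (IIGI) analyte series, assigns
    dominant and co-dominant subphenotypes by standardized deviance scores,
    and predicts subphenotype classes from the shape of 16-point OGTT and
    at-home continuous glucose monitor (CGM) curves. Includes C-peptide
    deconvolution through a two-compartment kinetic model, disposition index
    and incretin-effect calculators, a hepatic insulin-resistance index,
    engineered glucose-curve features, a smoothing-spline plus PCA reduced
    curve representation, a repeated stratified cross-validation classifier
    benchmark, CGM concordance analysis, and a synthetic cohort generator so
    the whole pipeline is testable without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    yaml,
    glmnet,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
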