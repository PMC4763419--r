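Package: trauma24
Title: Updating and Temporal Validation of Early Trauma Mortality Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for updating and temporally validating clinical prediction
    models of 24-hour in-hospital trauma mortality. Provides restricted cubic
    spline logistic risk models of systolic blood pressure, heart rate and
    Glasgow coma scale; re-estimation updating with a bootstrap linear
    shrinkage factor; per-hospital multiple imputation by chained equations
    with predictive mean matching; discrimination and calibration assessment
    pooled across imputations by medians; decision curve analysis with net
    benefit and avoided unnecessary-survey counts; and a colour-coded bedside
    risk chart over systolic blood pressure and coma scale. A synthetic
    multi-hospital cohort generator emulates the marginal distributions,
    missingness fractions and event rate of an urban Indian trauma registry
    so the full two-step updating/validation pipeline can be exercised and
    tested end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    pROC,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
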