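Package: regionrisk
Title: Model-Based Synthetic Estimation of Regional Suicide Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting the population (regional) risk of suicide
    from routinely collected administrative-style records. Implements
    sex-specific case-control logistic model development (LASSO screening,
    correlation filtering, backward selection, discrimination and calibration
    diagnostics), conversion of individual-level models into region-level
    model-based synthetic estimators via intercept correction and covariate
    aggregation, and a validation battery for regional risk forecasts (MAE,
    RMSE, top-k high-risk region identification). Includes a synthetic
    population generator with lookback-window event histories so the full
    pipeline can be exercised and tested without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    lubridate,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
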