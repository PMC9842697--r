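Package: patflux
Title: Refractometry-Based Bioprocess Monitoring, pH Probing and
    pH-Constrained Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for process-analytical-technology (PAT) driven analysis
    of upstream mammalian bioprocesses monitored by in-situ refractometry.
    Provides a synthetic bioprocess generator with known ground truth
    (SCADA, refractive-index and offline sample streams), derivation of the
    metabolic rate index (MRI) from the process trend index (PTI) by local
    quadratic filtering, missing-data handling (moving-average and
    Kalman/ARIMA imputation with a missingness gate), dynamic-time-warping
    and Pearson feature analysis, window-based and univariate forecasting
    harnesses with time-series cross-validation, scripted and autonomous
    MRI-driven pH setpoint probing against the simulated plant, and a
    constraint-based metabolic modelling core (FBA/FVA on JSON or SBML
    models) with an extracellular-pH constraint strategy, sodium/potassium
    exchange extension and gluconeogenesis blocking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
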