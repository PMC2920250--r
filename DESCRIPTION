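Package: otcsurv
Title: Syndromic Surveillance of Gastrointestinal Illness from
    Over-the-Counter Remedy Sales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating over-the-counter diarrheal-remedy sales as
    a syndromic indicator of gastrointestinal disease.  Provides weekly
    Sunday-anchored aggregation of sales, case-report and outbreak data,
    Box-Jenkins ARIMA modelling by conditional least squares, pre-whitened
    cross-correlation between sales and case series, regression of sales
    model residuals on outbreak covariates, rolling one-week-ahead forecast
    alarms from the upper 95% forecast limit, and outbreak-week
    sensitivity/specificity scoring against a random-signal null.  A
    synthetic-data generator reproduces the statistical structure of the
    surveillance setting so the whole pipeline is testable without
    proprietary retail data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
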