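Package: climmed
Title: Parallel Multiple Mediation of Climate Effects on Overweight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilevel parallel multiple-mediation analysis of the effect of
    ambient temperature on overweight and obesity, with fruit/vegetable
    consumption and physical-activity level as parallel mediators. Fits the
    structural equations (logistic, multinomial logistic, and
    province-clustered random-intercept logistic), decomposes effects into
    direct, path-specific indirect and total components on the log-odds
    scale, contrasts indirect pathways via the raw difference, and attaches
    percentile-bootstrap confidence intervals. Includes a synthetic-cohort
    generator with deterministic calibration of equation intercepts to target
    marginal prevalences, descriptive comparison tables, and an end-to-end
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    nnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
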