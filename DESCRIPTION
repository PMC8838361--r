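Package: usualintake
Title: Usual Dietary Intake Estimation from Short Runs of 24-Hour Recalls
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the usual (long-run average) daily intake of foods and
    nutrients from short windows of repeated 24-hour dietary recalls.
    Implements a two-part nonlinear mixed-effects estimator in the style of
    the National Cancer Institute method (probability of consumption by
    mixed-effects logistic regression, consumption-day amounts by a Box-Cox
    transformed linear mixed model, optionally with correlated person-level
    random effects), a Multiple-Source-Method-style estimator (per-person
    consumption probability combined with regression-residual shrinkage on a
    two-parameter Box-Cox scale), and the naive within-person short-window
    mean. Includes a calibrated synthetic recall generator with known
    ground-truth usual intakes, group-level (percentage-difference of means
    and percentiles) and individual-level (mean absolute error, mean absolute
    percentage error) validation metrics, and an orchestrated study runner
    producing season-by-season comparison tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
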