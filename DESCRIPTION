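Package: radonpt
Title: Proficiency Testing of Indoor Radon Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for interlaboratory comparisons (proficiency
    tests) of indoor radon exposure measurements performed with passive
    detectors and active monitors. Computes robust consensus assigned values
    and their uncertainty per exposure window with the iterative robust
    estimator of ISO 13528:2015 (Algorithm A), scores each participant with
    the relative percentage difference D(%), the zeta score and the z-score,
    classifies performance against the standard 2.0/3.0 thresholds, screens
    outliers with the 1.5 IQR boxplot rule, and renders campaign reports.
    Includes a seeded synthetic-campaign generator (radon-chamber
    concentration dynamics, passive detector groups, active monitors with
    counting statistics, and a holder-degassing contamination mechanism) so
    the whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
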