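Package: foodtweetenv
Title: Twitter-Derived Neighborhood Food Environment Indicators and
    Chronic Disease Prevalence
Version: 0.1.0
Authors@R:
    person("Maintainer", "foodtweetenv", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline that turns geotagged short-text
    posts into census-tract food-environment indicators (mean caloric
    density per food post, percent healthy-food mentions, percent
    fast-food mentions) and relates them to tract-level chronic-disease
    prevalence (obesity, diabetes, hypertension).  Includes lexicon-based
    food-term matching, point-in-polygon tract assignment, tract
    aggregation with a minimum-post filter and z-standardization, median
    (least-absolute-deviation) regression with bootstrap standard errors
    plus an exact linear-programming oracle, ordinary least squares
    sensitivity models, generalized estimating equations for state-level
    temporal trends, a Chow test for group differences, and a
    synthetic-data generator with planted effects so that the whole
    analysis is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
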