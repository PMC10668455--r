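Package: longdens
Title: Longitudinal Breast Density from Serial BI-RADS Readings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequential empirical-Bayes estimation of a woman's continuous
    breast density from her full history of BI-RADS screening readings,
    using a linear mixed model with random intercept and age slope. Includes
    the derived eight-category density measure, time-varying-covariate Cox
    proportional-hazards evaluation with likelihood-ratio information gain,
    a yearly at-risk concordance index with cluster bootstrap, a
    screen-to-screen risk-stability analysis, and a synthetic
    screening-cohort simulator with known generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
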