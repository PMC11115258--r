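Package: crshape
Title: Simulation Tests for Apparent Supralinearity in PM2.5
    Concentration-Response Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates city-structured mortality cohorts under linear and
    supralinear concentration-response (C-R) functions for fine particulate
    matter (PM2.5) and assesses how spatial variation in PM toxicity,
    confounders correlated with PM2.5, and classical exposure measurement
    error can make a truly linear C-R function appear supralinear. Provides
    a life-table-driven discrete-time cohort simulator, a grouped-data Cox
    proportional-hazards fitter with natural cubic spline exposure terms,
    slope-ratio and AIC-difference shape tests, and scenario-grid experiment
    runners that tabulate detection frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    splines,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
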