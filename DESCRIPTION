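Package: carpop
Title: Population Displacement Estimation from Satellite Car Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating internal population displacement from
    satellite-derived car detections. Implements confidence-threshold tuning
    of an object detector by F-beta sweep, exclusion-polygon false-positive
    filtering, population-representativeness and cloud screening of image
    footprints, 1 km gridded car dynamics with quarterly and yearly relative
    change up to administrative-unit level, and two baseline population-car
    linkage models (a per-cell ratio estimator with global-median imputation
    and a penalized cubic-spline Poisson regression) that bracket predicted
    population change. Includes a fully specified synthetic geospatial world
    generator with known ground truth for end-to-end validation, an
    imagery-feature diagnostic model of log car density, and a deterministic
    pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mgcv,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
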