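Package: occpart
Title: Dynamic Correlated-Detection Occupancy Models with Deviance
    Partitioning
Version: 0.1.0
Authors@R:
    person("BBS", "Dynamics Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits multi-season (dynamic) occupancy models to stop-level
    roadside survey data in which detections are spatially correlated
    along the route (Markovian availability between consecutive stops)
    and detection heterogeneity across routes is captured by a two-class
    finite mixture.  Provides the six-model analysis-of-deviance (RDev2)
    machinery for partitioning temporal variation in colonization and
    extinction into climate and land-cover components, Hosmer-Lemeshow
    goodness-of-fit tests on naive turnover rates, thermal-stress
    covariate engineering from daily temperature extremes, and a
    synthetic-data generator emulating Breeding Bird Survey route
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
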