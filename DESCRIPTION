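Package: discorient
Title: Orientation and Swimming Behavior of Fish Larvae in Drifting In
    Situ Chamber Deployments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing the in situ orientation behavior of
    larval fishes observed in a drifting in situ chamber (DISC): circular
    statistics (mean bearing, mean resultant length, first- and
    second-order Rayleigh tests of uniformity), trajectory kinematics
    (swimming speed, turning angle), compass-based correction from the
    rotating camera frame to the cardinal frame with device-bias
    filtering, per-deployment reference directions (sun azimuth, natal
    reef bearing, current drift, wind) and the associated
    hypothesis-testing battery, ontogenetic regressions of behavior on
    age, and a seeded biased correlated random-walk simulator of
    DISC-like cohorts implementing alternative orientation strategies
    with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
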