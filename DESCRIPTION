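Package: silentfail
Title: Modelling Driver Takeover Responses to Silent Automated-Vehicle Failures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how supervising drivers detect and respond to
    silent (unalerted) failures of automated lane keeping. Provides failure
    kinematics on curved roads (time-to-lane-crossing computation, inverse
    design of yaw-rate offsets from a target criticality, low-discrepancy
    generation of failure conditions), a synthetic takeover-study generator
    with hierarchical participant effects, truncation and censoring, Bayesian
    hierarchical distributional models of takeover timing (truncated/censored
    heteroscedastic normal) and of maximum steering correction (log-log power
    law) fitted by MCMC, and posterior-predictive machinery for predictive
    intervals, variance decomposition and road-departure risk curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
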