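Package: lcgate
Title: Learning-Curve Segmentation and Poisson Dispersion Gating for
    Surgical-Simulation Attempt Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess technical-skill acquisition from attempt-level
    surgical-simulation records. Computes the cumulative major-mistake-average
    (MMA) learning curve, segments it into learning periods with absolute-drop
    and drop-rate statistics, fits linear and exponential trends with R
    squared, and applies Poisson dispersion and goodness-of-fit tests to
    per-period major-mistake counts to detect the plateau at which residual
    errors occur randomly (an operational "efficient skill threshold").
    Includes a three-phase Bernoulli-hazard simulator of attempt sequences for
    calibration, power, and parameter-recovery studies, plus a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
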