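Package: hipcea
Title: Cost-Utility Analysis of Hip Resurfacing Versus Total Hip Replacement
Version: 0.1.0
Authors@R:
    person("hipcea", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registry-style lifetime cost-utility analysis of metal-on-metal
    hip resurfacing (RS) against total hip replacement (THR). Provides a
    synthetic joint-registry generator with known ground truth, Kaplan-Meier
    and flexible parametric (Royston-Parmar spline) time-to-revision models
    with extrapolation, classification of device-patient subgroups against
    the NICE benchmark of less than 5% revision at 10 years, a four-state
    semi-Markov annual-cycle cohort model producing discounted costs and
    QALYs, probabilistic sensitivity analysis with Beta/Gamma input
    distributions, and cost-effectiveness reporting (ICERs, dominance,
    acceptability curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
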