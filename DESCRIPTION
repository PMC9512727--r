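Package: owncontrol
Title: Own-Control Analysis of Osteoporosis Treatment Effectiveness from
    Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the real-world effectiveness of
    osteoporosis medications from administrative claims using a
    self-controlled (own-control) cohort design.  The package builds
    new-user treatment cohorts with hierarchical class assignment,
    constructs treatment episodes with a refill-gap persistence
    algorithm, adjudicates osteoporotic fracture events from diagnosis
    and procedure claims, partitions as-treated person-time into an
    early-treatment baseline window and successive on-treatment windows,
    and estimates incidence rate ratios with Wald and exact-conditional
    confidence intervals, weighted linear trends in fracture rates, and
    an age-adjusted conditional Poisson model.  A configurable synthetic
    claims generator with known piecewise-constant fracture hazards
    provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
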