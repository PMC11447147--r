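Package: dyadscan
Title: Family-History Transmission-Pattern Analysis for Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control family-history analyses of dementia risk:
    parent-to-offspring dyad exposure tables, risk and odds ratios with Wald
    confidence intervals, relative-ratio comparisons between transmission
    routes (with a Woolf-variance z test), descriptive group comparisons,
    endophenotype linear models and a logistic disease-risk model including a
    same-birthplace remote-consanguinity proxy. A generative simulator of
    X-linked, Y-linked and recessive/consanguinity risk transmission with
    case-control ascertainment makes every pipeline stage testable at desk
    scale, including Monte-Carlo calibration of the dyad-comparison test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
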