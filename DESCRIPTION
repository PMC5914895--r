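Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis for Cluster-Randomised Interventions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An ingredients-based costing and cost-effectiveness pipeline for
    cluster-randomised trials of public-health interventions. Converts a
    multi-currency, multi-year cost ledger into base-year economic costs with
    capital annualisation (equivalent annual cost) and shared-cost allocation;
    estimates adjusted risk differences on a binary outcome with cluster-robust
    sandwich standard errors; converts effects into counterfactual cases
    averted; computes cost per case averted against a do-nothing comparator;
    and runs univariate (tornado) sensitivity analysis. Includes a synthetic
    cluster-trial and cost-ledger generator with known ground truth, a built-in
    worked example based on a published school violence-prevention programme in
    Uganda, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
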