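Package: ocsdce
Title: Discrete Choice Experiment Analysis of Oral Corticosteroid
    Risk-Benefit Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing, simulating and analysing discrete choice
    experiments (DCEs) on the risk-benefit balance of oral corticosteroid
    (OCS) treatment for asthma attacks.  Provides Bayesian D-efficient
    generation of blocked two-alternative choice tasks, calibrated synthetic
    respondent rosters and choice simulation under a random-utility model,
    maximum-likelihood multinomial logit estimation with analytic
    derivatives (model-based and respondent-clustered covariances, weighted
    and interaction models), and post-estimation inference: odds ratios,
    marginal rates of substitution with delta-method and Krinsky-Robb
    intervals, and choice-share forecasting for hypothetical treatment
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
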