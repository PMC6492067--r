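Package: appmultiplier
Title: Hidden-Population Size Estimation with the Social-App Multiplier Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the size of hidden populations (such as men
    who have sex with men reachable through dating apps) by the social-app
    multiplier method: counting active app users (deduplicated enumeration,
    two-sample capture-recapture, or a provider-supplied aggregate),
    estimating the proportion of the population using the app from a
    respondent-driven sampling (RDS) survey with the Salganik-Heckathorn
    (RDS-I) and Gile's successive-sampling (SS) estimators and
    chain-structured bootstrap confidence intervals, running the standard RDS
    diagnostic battery (recruitment homophily, convergence, bottleneck,
    sensitivity) with an explicit estimator-selection rule, dividing count by
    proportion to obtain provincial population sizes, and extrapolating to a
    national total with age-weighted percentages. A network-based RDS
    simulator with known ground truth supports parameter-recovery validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
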