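Package: fluxinvert
Title: Inverse Prediction of Growth Environments from Metabolic Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state metabolic fluxes of a constraint-based
    metabolic model under composed growth environments (a primary carbon
    source, a primary nitrogen source, and randomly sampled low-level
    impurities) using flux balance analysis, and then predicts the growth
    environment back from the internal fluxes alone with L1-regularized
    multinomial logistic regression. Includes readers for BiGG JSON and
    SBML (FBC) models, reaction classification into exchange, transport,
    biomass and internal sets, parsimonious secondary flux minimization,
    joint and separate carbon/nitrogen classifiers with cross-validated
    penalty selection, predictive-reaction extraction, single-reaction
    ablation, a novel-substrate extrapolation protocol, and a synthetic
    toy-network generator with tunable substrate-signature overlap so the
    whole pipeline is testable without a genome-scale model download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
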