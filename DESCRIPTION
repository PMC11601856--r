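Package: smokecarbon
Title: Estimation of Background and Fire-Smoke Carbonaceous PM2.5 with a
    Residual-Adjusted Super Learner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-level residual-adjusted super learner for calibrating
    paired chemical-transport-model simulations of carbonaceous fine
    particulate matter (organic and elemental carbon) against ground
    monitor observations, separating background from fire-smoke
    concentrations.  Includes scenario classification from smoke-on and
    smoke-off simulation pairs, SMOTE enrichment of skewed training data,
    stacked ensembles of heterogeneous base learners with out-of-fold
    meta-learning, generalized-additive-model residual adjustment of
    monthly fields, three cross-validation schemes (random, clustered
    spatial, leave-one-year-out), population exposure accounting
    (heavy-fire-smoke person-days), and attributable-mortality and
    value-of-statistical-life monetization pathways.  A synthetic-data
    generator with known ground truth makes every stage testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    ranger,
    xgboost,
    glmnet,
    caret,
    pracma,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
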