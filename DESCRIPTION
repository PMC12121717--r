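Package: grayzone
Title: Survival-Supervised Gray-Zone Derivation for MGMT Promoter
    Methylation Pyrosequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives the optimal "gray zone" of intermediate MGMT promoter
    methylation from pyrosequencing data with paired overall-survival
    follow-up. Provides replicate quality control and aggregation for
    per-CpG pyrosequencing runs, Mahalanobis multivariate outlier
    flagging, a self-contained Kaplan-Meier and Cox proportional-hazards
    engine with Efron tie handling, and a survival-supervised grid search
    over three-category methylation classifications in which the optimal
    gray zone is selected by dual hazard-ratio significance against the
    gray-zone reference plus the maximal nested likelihood-ratio
    statistic. Includes a synthetic-cohort generator emulating bimodal,
    strongly correlated CpG methylation profiles with replicate noise and
    category-dependent proportional hazards, and a command-line interface
    for laboratory pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
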