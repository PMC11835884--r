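Package: branchgrowth
Title: Annual Branch Growth Modelling for Korean Pine Under Competition and Climate
Version: 0.1.0
Authors@R:
    person("Forest", "Modelling", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing annual branch length and diameter growth in
    monopodial conifers such as Korean pine (Pinus koraiensis). Provides a
    synthetic stand and branch-chronology generator with the hierarchical
    structure of a felled-tree branch study; retrospective reconstruction of
    tree diameter and height chronologies from ring widths and whorl geometry;
    annual distance-dependent (Hegyi) and basal-area competition indices;
    log-linear growth models with tree-level random intercepts, optional AR(1)
    within-branch errors, REML estimation and BLUP calibration; hierarchical
    partitioning of predictor-group importance; leave-one-tree-out
    cross-validation; and a pipeline with stable CSV schemas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
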