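Package: enmopt
Title: Multi-Objective Tuning of Maximum-Entropy Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background ecological niche modelling with an
    L1-regularised maximum-entropy (Gibbs) core and NSGA-III multi-objective
    hyperparameter tuning over feature classes and regularisation multipliers
    against four objectives (test AUC, TSS, 10% omission rate, AICc).
    Includes spatial thinning of occurrence records, variable screening by
    Spearman correlation, variance inflation and model-based importance,
    MESS extrapolation surfaces, MTSS-based habitat classification with
    range-dynamics and centroid-migration summaries, livestock exposure-risk
    overlays with Jenks natural-breaks classes, and a seeded synthetic
    landscape generator so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
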