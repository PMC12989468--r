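Package: gymbiome
Title: Resistance-Training Gut Microbiome Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Longitudinal analysis of gut microbiome responses to an 8-week
    resistance training intervention: strength metrics from session-level
    training logs, responder stratification, rarefaction-based alpha and
    Bray-Curtis beta diversity, within-subject community-shift statistics, a
    paired bias-corrected differential-abundance test with Dunnett-type
    timepoint contrasts, and a permutation-subset robustness procedure that
    calibrates discoveries against random non-responder subsets. A seeded
    synthetic-study generator (cohort, training logs, ASV tables with planted
    responder-linked effects, metabolite panel, diet records) makes every
    stage testable without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
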