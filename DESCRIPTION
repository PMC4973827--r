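Package: VariantCLM
Title: Bayesian Cumulative Link Calibration of Variant Deleteriousness Scores
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrates a continuous deleteriousness score (such as the scaled
    CADD C-score) against ordinal expert pathogenicity classes using a Bayesian
    cumulative link (proportional-odds) model. Provides MCMC inference with
    convergence diagnostics, posterior mean-deviance discrepancy flagging,
    observed-versus-model class reassignment matrices, prioritization of
    variants of uncertain significance by model probability of the extreme
    classes, and a second-tier override of score-based benign calls using
    qualitative effect-impact annotations. Includes synthetic-data generators
    emulating the per-class score structure of expert-curated mismatch-repair
    gene variant sets, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: VariantAnnotation, Classification, Bayesian, Regression, Software
RoxygenNote: 7.3.3
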