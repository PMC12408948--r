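Package: debipm
Title: Dynamic Energy Budget Integral Projection Models for Comparative
    Life-History Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds length-structured integral projection models from
    Kooijman-Metz dynamic energy budget parameters, derives life-history
    traits (generation time, age at maturity, progressive and retrogressive
    growth, recruitment success, iteroparity, net reproductive rate, mature
    life expectancy) together with population growth rate and the damping
    ratio, and runs a comparative layer: phylogenetically corrected
    varimax-rotated principal component analysis with Pagel's lambda,
    body-mass correction, and downstream linear, mixed and ordinal models.
    Includes a synthetic-study generator (species parameters, Yule
    phylogenies, Brownian-motion traits, covariates) so the whole pipeline
    is testable end to end with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
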