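Package: mindev
Title: Morphometric Similarity Networks and Normative Deviation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds Morphometric Inverse Divergence (MIND) structural
    similarity networks from vertex-level cortical features, fits per-region
    normative models of weighted network degree with sinh-arcsinh likelihoods
    and partially pooled site effects, scores individual deviations as
    Z-scores, and runs the downstream analyses of a dementia imaging study:
    extreme-deviation overlap and difference maps with permutation inference,
    functional-network enrichment under group-label and spatial rotation
    nulls, spin-test spatial decoding against regional reference maps, and
    clinical models of deviation burden (ANOVA, nested APOE regressions, Cox
    survival, ordinal neuropathology models). A synthetic multi-site cohort
    generator with injectable network-targeted disease effects supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    lmtest,
    multcomp,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
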