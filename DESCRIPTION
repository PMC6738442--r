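Package: ccamode
Title: Brain-Behavior Modes of Covariation via Canonical Correlation
    Analysis with Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for relating structural brain
    imaging-derived phenotypes (IDPs) to cognitive, demographic, health and
    lifestyle measures (non-IDPs) in a late-midlife birth cohort setting:
    rank-based inverse normal transformation, confound regression,
    soft-impute matrix completion, residualized and raw-difference cognitive
    change scores with extreme-group selection, mass-univariate correlation
    screening with Bonferroni and Benjamini-Hochberg control, and
    PCA-reduced canonical correlation analysis with max-statistic
    permutation familywise inference, canonical structure loadings,
    subdomain importance summaries and Tucker factor congruence. Includes a
    synthetic cohort generator with a planted latent brain-behavior mode so
    every stage is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
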