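Package: badgemeta
Title: Phylogenetic Multilevel Meta-Analysis for Status-Badge Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-analysing comparative evidence on the badge-of-status
    hypothesis (the association between coloration and aggression across
    animals). Converts heterogeneous reported statistics (Pearson r,
    means/SDs/sample sizes, t, F, chi-squared) into signed correlation-scale
    effect sizes with sampling variances, including a corrected and a
    deliberately erroneous biserial computation for auditing; builds
    phylogenetic correlation matrices from Newick trees with Grafen branch
    lengths; fits phylogenetic multilevel random-effects meta-analyses and
    meta-regressions by restricted maximum likelihood with a within-study
    block sampling variance-covariance structure; decomposes heterogeneity
    into multilevel I2 with prediction intervals and marginal R2; tests for
    small-study effects by precision-moderator meta-regression; and simulates
    complete synthetic datasets with known truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
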