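Package: scnets
Title: Structural Covariance Network Analysis of Cortical Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from regional
    cortical morphometrics (surface area or thickness), computes global and
    nodal graph-topology metrics across a sparsity range with normalization
    against degree-preserving rewired null networks, and compares two groups
    with a subject-relabeling permutation test summarized by the area under
    the metric-by-sparsity curve. Includes covariate residualization,
    normality-gated demographic comparisons, covariate-adjusted partial
    correlation, and a block-covariance synthetic cohort generator so the
    whole pipeline can be exercised without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
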