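Package: paca
Title: Phenotype-Aware Component Analysis for Case-Specific Variation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive dimensionality reduction for case/control omics
    matrices. Learns the axes of variation specific to a case group by
    removing, via canonical correlation analysis carried out over the sample
    space, the sources of variation shared between a case matrix and a
    control matrix, and then applying principal component analysis to the
    residual. Includes permutation-based selection of the number of shared
    directions to remove, a randomized extension for the
    more-samples-than-features regime, projection of fitted loadings onto
    replication cohorts, standard PCA and contrastive PCA baselines, and a
    generative simulator of the underlying low-rank case/control factor
    model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
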