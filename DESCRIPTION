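Package: gpnet
Title: Genome-Enabled Prediction with Single-Hidden-Layer Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-enabled prediction of quantitative traits with a
    single-hidden-layer feed-forward neural network trained by regularized
    back-propagation. Supports three genomic covariate structures for the
    network input: the raw SNP marker matrix coded -1/0/1, the standardized
    (VanRaden-type) genomic relationship matrix G, and principal-component
    scores UD from the singular value decomposition of the marker matrix.
    Includes marker quality control, min-max feature scaling, phenotype
    normalization with exact back-transform, a one-neuron linear network
    configuration that approximates GBLUP together with a closed-form ridge
    regression oracle, repeated k-fold cross-validation scored by Pearson
    correlation, and a synthetic genotype-phenotype simulator with additive
    and epistatic architectures for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
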