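Package: cortexg
Title: Cortical Gene Expression Components and Their Association with
    General Cognitive Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An imaging-transcriptomics pipeline linking the major spatial
    components of cortical gene expression to meta-analytic regional
    correlates of general cognitive functioning (g). Provides donor
    consistency quality control and hemisphere-wise rescaling of regional
    expression matrices, correlation-matrix principal components with
    varimax rotation and a Tucker-congruence stability/validation suite,
    one-factor latent-g confirmatory factor models with full-information
    maximum likelihood, per-region standardised g-morphometry associations,
    DerSimonian-Laird random-effects meta-analysis with age-moderation
    meta-regression, spherical spin-permutation spatial null models, and
    component-adjusted single-gene and cell-type association mapping.
    Includes synthetic-data generators with known ground truth for every
    pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils
Suggests:
    metafor,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
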