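Package: littertraits
Title: Global Analysis of Riparian Litter Traits, Environment and Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of riparian plant litter traits
    along global environmental gradients. Grafts study species onto a dated
    backbone phylogeny using taxonomy-based nearest-relative placement with
    distance-conserving random polytomy resolution, estimates phylogenetic
    signal (Pagel's lambda) by maximum likelihood with a likelihood-ratio
    test, models trait-environment relationships with heteroscedastic
    generalized least squares (per-site variance weights), AIC backward
    selection and LMG relative-importance decomposition with bootstrap
    confidence intervals, and summarises multivariate structure with PCA and
    penalized-spline latitudinal trends. Includes seeded generators for
    synthetic trees, taxonomies, site environments and trait tables that
    emulate the design of a global litter-quality survey, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
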