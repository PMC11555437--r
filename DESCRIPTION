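Package: OmniK
Title: Kernel Machine Regression for Jointly Testing Main and
    Treatment-Interaction Effects of Microbial Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A general kernel machine regression framework for testing
    whether microbial (or any) variants underlying an input kernel are
    associated with a continuous or binary response, either directly
    (main effects), through interaction with a treatment, or both.
    Surrogate variants are extracted from any positive semi-definite
    kernel by singular value decomposition, three endogenous kernels
    (main, interaction, both) are formed, and variance-component score
    statistics are calibrated by residual permutation.  Per-kernel
    results are combined across the three endogenous targets, and
    across multiple ecological input kernels (Jaccard, Bray-Curtis and
    the UniFrac family), by a two-level minimum-P omnibus (OmniK) that
    controls the family-wise error under dependence.  Includes a
    Dirichlet-multinomial simulation harness for type-I-error and power
    experiments, and Fisher/Brown/Simes comparison combiners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    biomformat,
    optparse,
    yaml
Config/testthat/edition: 3
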