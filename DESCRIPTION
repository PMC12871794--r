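Package: scaleGxE
Title: Scale-Aware Testing of Polygenic Score by Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinguishes scale-dependent from scale-independent
    gene-environment interactions in quantitative traits. Profiles the
    p-value of a polygenic score by environment (PGSxE) interaction term
    across a grid of Box-Cox power transformations of the phenotype and
    under rank inverse normal transformation (RINT), classifies
    interactions as scale-dependent or scale-independent, and provides the
    generative simulation machinery to study calibration, inflation and
    power of these tests. Also includes desk-scale GWAS with greedy LD
    clumping, min-p shared-hit identification between two GWAS, p-value
    threshold polygenic score construction, scale-aware score evaluation
    (including relative R-squared between log- and default-scale scores),
    and a naive effect-size genetic correlation over independent SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    sandwich,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
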