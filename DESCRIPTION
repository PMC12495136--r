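Package: yewoffset
Title: Genomic Offset and Genotype-Environment Association Pipeline for
    Climate (Mal)Adaptation in Forest Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify climate (mal)adaptation in range-wide
    population samples of long-lived trees such as European yew (Taxus
    baccata). Implements genotype filtering, modal-genotype imputation
    by gene pool and linkage pruning; permutation-based forward
    selection of climate predictors with correlation and
    variance-inflation pruning and distance-based Moran eigenvector
    maps; genotype-environment association scans by redundancy analysis
    (with Mahalanobis outlier detection), latent-factor ridge
    regression, and per-locus random-forest importance, combined into
    consensus candidate sets with frequency-matched random controls;
    redundancy-analysis and gradient-forest genomic offsets with
    multi-GCM averaging and five-class robustness flags; a genomic
    discrepancy index contrasting observed and climate-predicted
    ordination scores; population-specific FST and Jost's D; and
    validation of offsets against common-garden trait BLUPs and a
    composite trait index. A synthetic-landscape generator with known
    adaptive architecture makes every stage testable without deposited
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    vegan,
    geosphere,
    ranger,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
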