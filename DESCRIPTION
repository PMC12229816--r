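Package: reefshift
Title: Detecting Non-Random Lineage Frequency Shifts on Restored Oyster Reefs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temporal shifts in the frequencies of
    genetic clusters on restored shellfish reefs sampled at two censuses.
    Provides a synthetic-data generator for multi-source restoration
    cohorts with known truth (Balding-Nichols divergence, family
    structure, cluster-specific survival, batch-structured missingness),
    an iterative SNP/individual filtering cascade with sliding-window LD
    pruning, DAPC-style genetic cluster inference (k-means on principal
    component scores with BIC/delta-K selection and linear discriminant
    posteriors), three complementary frequency-shift inferences (exact
    hypergeometric tests with Benjamini-Hochberg correction and a
    within-reef permutation null, fixed-effects beta-binomial regression
    with year contrasts, and compositional CLR + PERMANOVA), genetic
    diversity and relatedness estimators (observed and expected
    heterozygosity, FIS with locus bootstrap, rarefied allelic richness,
    Weir-Cockerham FST, Wang pairwise relatedness with individual
    bootstrap), and trait-to-mortality multiple regression with influence
    diagnostics and added-variable decompositions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    glmmTMB,
    MASS,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
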