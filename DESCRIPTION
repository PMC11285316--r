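Package: metaconcord
Title: Concordance Analysis of Paired 16S rRNA and Shotgun Microbiome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing microbial community profiles obtained from
    the same samples by two sequencing platforms (16S rRNA amplicon and whole
    shotgun metagenomics). Implements taxonomy harmonization across reference
    databases (synonym mapping, rank aggregation, merging of ambiguous
    slash-named amplicon taxa), compositional preprocessing (genome-length
    normalization, prevalence/abundance filtering, Bayesian-multiplicative
    zero replacement, centered log-ratio transform), taxonomic and abundance
    concordance statistics (overlap accounting, Cohen's kappa on
    median-binarized abundances, Spearman correlation of compositional
    centres), alpha-diversity comparison with rarefaction (Shannon, Chao1),
    beta-diversity comparison (Aitchison distance, principal coordinates,
    ANOSIM, PERMANOVA with pairwise post-hoc tests, Procrustes, RV
    co-inertia coefficient and an RV-matrix principal component summary),
    and cross-platform machine-learning concordance (one-vs-one linear
    support vector machines and random forests, prediction agreement,
    support-vector matching and microbial-signature similarity). A synthetic
    paired-platform study generator provides fully reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    e1071,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
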