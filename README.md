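# metaconcord

Concordance analysis of paired 16S rRNA amplicon and whole-shotgun
metagenomic profiles of the same samples.

## The problem

Gut-microbiome studies profile communities either by 16S rRNA gene amplicon
sequencing or by whole shotgun metagenomics. The two platforms use different
reference databases, depths and detection characteristics, so studies using
one are hard to reconcile with studies using the other. When the *same*
stool samples are sequenced both ways — as in colorectal-cancer screening
cohorts with three diagnosis groups (healthy controls, advanced/high-risk
colorectal lesions, CRC cases) — one can quantify exactly where the
platforms agree: which taxa both detect, whether abundances correlate,
whether alpha- and beta-diversity structure is preserved, and whether
machine-learning models trained on each platform make concordant diagnoses
and select concordant microbial signatures.

`metaconcord` implements that comparison as a tested, reusable pipeline for
people running paired-platform studies: harmonize taxonomy across
databases, preprocess compositionally, and measure concordance at every
level, from taxon overlap to classifier agreement. A synthetic
paired-platform generator with planted ground truth makes every stage
testable offline.

## Methods at a glance

* **Taxonomy harmonization** — user-supplied synonym maps applied per rank
  (`normalize_names`), aggregation to genus/family/… (`aggregate_rank`),
  transitive merging of ambiguous slash-named 16S taxa such as
  *Blautia obeum/wexlerae* (`merge_ambiguous`), exclusion of accession-only
  taxa like `MGYG…` (`exclude_unnamed`). Per-sample count totals are
  conserved exactly.
* **Compositional preprocessing** — genome-length normalization of shotgun
  counts; retention of taxa reaching 0.1% relative abundance in at least 5%
  of samples; Bayesian-multiplicative zero replacement with a
  square-root-of-depth prior strength; the centered log-ratio transform
  `clr(x)_j = ln(x_j / g(x))`; median binarization for agreement
  statistics.
* **Concordance statistics** — global and per-sample taxon overlap;
  unweighted Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)` on median-binarized
  abundances; Spearman correlation of the platforms' compositional centres
  (closed geometric means) over shared taxa.
* **Diversity** — Shannon entropy after rarefying each sample to the
  platform's minimum depth, bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))` from raw counts, Wilcoxon tests between
  platforms and Spearman correlation across platforms; per-sample sparsity
  with Kruskal–Wallis tests across diagnosis groups.
* **Beta diversity** — Aitchison distance (Euclidean on clr), principal
  coordinates, ANOSIM and PERMANOVA (999 permutations, pairwise post-hoc
  with Benjamini–Hochberg correction), symmetric Procrustes
  `r = √(1 − m²)` between the two platforms' ordinations, the RV
  co-inertia coefficient, and a PCA of the 6×6 matrix **K** of pairwise RV
  coefficients (2 platforms × 3 ranks) via `K = UΛ²Uᵀ` with projections
  `UΛ`.
* **ML concordance** — one stratified train/test split reused everywhere;
  one-vs-one linear SVMs (cost grid 0.1–100) and random forests
  (500–2000 trees, node size 2–3) tuned by 5-fold CV; test accuracy with
  bootstrap CIs (n = 2000); cross-platform prediction agreement and kappa;
  support-vector matching; Kendall tau-b and top-k overlap of
  importance-ranked microbial signatures.

## Worked example

```r
library(metaconcord)

sim <- simulate_paired_study(generator_config(
  n_control = 20, n_hrl = 20, n_crc = 20, n_species = 150, seed = 42))
study <- sim$study
study$x16s <- merge_ambiguous(study$x16s)   # collapse slash-taxa

res <- concordance(study, ranks = c("species", "genus"),
                   ml_ranks = "species", seed = 42)
res
#> platform_concordance over ranks: species, genus
#>  species shared 68 (74.7%/50.4%) | centre rho 0.93 | procrustes r 0.87 | RV 0.75
#>  genus   shared 43 (84.3%/86.0%) | centre rho 0.79 | procrustes r 0.81 | RV 0.69
#>  ML ranks: species

summary(res)
#>     rank n_16s n_shotgun n_shared centre_rho shannon_rho anosim_R_shotgun
#>  species    91       135       68      0.933       0.880            0.368
#>    genus    51        50       43      0.788       0.884            0.257
#>  anosim_R_16s procrustes_r    rv
#>         0.248        0.870 0.749
#>         0.214        0.805 0.688

res$ml$species$comparison$SVM$signature
#> signature_comparison: tau 0.49 (95% CI 0.27, 0.67); top-50 agreement 100% over 42 shared taxa
```

Reading the output: of the 135 species the synthetic shotgun platform
detects and the 91 the 16S platform detects, 68 are shared; the platforms'
average compositions over those shared species correlate strongly
(Spearman 0.93), sample ordinations match well (Procrustes r 0.87,
RV 0.75), and the two platforms' SVM models rank taxon importance
concordantly (Kendall tau 0.49), with the planted signature species
recovered by both. Genus-level numbers show the same pattern at coarser
resolution. `plot(res)` draws the paired Aitchison PCoAs colored by
diagnosis.

A thin CLI for shell use is installed at
`inst/scripts/metaconcord-cli.R` (subcommands `simulate` and `all`);
`run_all()` is the equivalent R entry point and writes tidy TSV reports
plus a JSON run manifest.

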