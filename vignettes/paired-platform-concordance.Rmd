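---
title: "Comparing paired 16S and shotgun microbiome profiles with metaconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired 16S and shotgun microbiome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconcord)
```

## The comparison problem

When the same stool samples are profiled by both 16S rRNA amplicon
sequencing and whole shotgun metagenomics, the two resulting count tables
describe one underlying community through two very different instruments.
Shotgun sequencing reads the whole genome pool at depths of millions of
reads per sample and resolves many species, but its counts scale with
genome length and its reference catalogues contain many accession-only
("unnamed") taxa. Amplicon sequencing reads a single marker gene at depths
of tens of thousands of reads, sees only the taxa its primers and database
cover, multiplies counts by the 16S copy number, and frequently cannot
resolve a read to a single species — producing slash-named candidate sets
such as *Blautia obeum/wexlerae*. `metaconcord` quantifies how much of the
community picture survives the change of instrument.

The package treats abundance data as compositional: only relative
information is meaningful, so all quantitative comparisons go through the
centered log-ratio (clr) transform and statistics that are invariant to
per-sample rescaling. Detection questions (which taxa are present) are
instead answered on raw counts, before any zero replacement, because
imputation would manufacture presence.

## Pipeline stages and their assumptions

**Harmonization.** Names are reconciled with user-supplied synonym maps
(no live taxonomy queries, for reproducibility); maps must be idempotent
and chains/cycles are rejected at construction. Ambiguous 16S taxa whose
candidate sets intersect are merged transitively; the merged taxon keeps
the genus written once with alphabetically sorted epithets. Counts are
summed in every merge, so each sample's total is conserved exactly — an
invariant the tests check on every harmonization operation. Taxa missing
the target aggregation rank go to an explicit `unassigned@rank` bucket:
it keeps compositions closed but is flagged unnamed so overlap statistics
compare only nameable units.

**Genome-length normalization.** Shotgun counts are divided by genome
length (bases) and each sample rescaled back to its original library
size. Because every downstream statistic is compositional, only the
within-sample proportions matter; the rescaling merely keeps the table on
a read-like scale for reporting.

**Filtering.** A taxon is retained if its within-sample relative abundance
reaches 0.1% in at least `ceiling(0.05 * n)` samples. The ceiling keeps
"at least 5% of samples" true when `n` is not divisible by 20. Relative
abundance is evaluated after genome-length normalization, which matches
the ordering of the preprocessing stages. The filter is monotone in both
thresholds (relaxing either never removes a retained taxon).

**Zero replacement.** Log-ratio analysis requires strictly positive
parts. Each sample is modelled as a multinomial with a uniform Dirichlet
prior whose total strength is the square root of the sample's depth
(`sqrt(n)`); the posterior expectation imputes each zero at
`sqrt(n) / (D (n + sqrt(n)))` of the composition, and the non-zero parts
are multiplicatively rescaled, preserving their ratios exactly. At large
depth with few taxa the raw posterior value can exceed the smallest
observed proportion, which would put imputed values above the detection
limit; the imputation is therefore capped at 0.65 times the sample's
minimum observed proportion. The cap constant follows the convention of
simple multiplicative replacement, where imputed values are placed at
roughly two-thirds of the detection limit.

**Diversity.** Shannon entropy is depth-sensitive, so each sample is
rarefied to its platform's minimum depth first; Chao1 uses singletons and
doubletons directly and is computed from raw counts (rarefaction or
normalization would destroy the rare tail it needs). The bias-corrected
Chao1 form is the default because the classic `F1²/(2 F2)` form is
undefined when no doubletons exist. Rarefaction is a single seeded
multivariate-hypergeometric draw per sample — deterministic reports, with
a mean-over-draws option — implemented by sequential `rhyper` draws so
that study-scale depths of millions of reads need no expanded read
vector. The platform comparison uses the unpaired Wilcoxon rank-sum test
as the headline (a paired signed-rank option exists); association is
reported as Spearman's rho by default, with Pearson's r alongside, since
rank correlation is the more defensible choice for diversity indices.

**Beta diversity.** The Aitchison distance (Euclidean on clr) feeds
classical PCoA; because the input is Euclidean, negative eigenvalues
beyond `1e-8` (relative) indicate a bug and are rejected rather than
silently clipped. PCoA of Aitchison distances is algebraically identical
to PCA of the clr matrix up to axis sign, which the tests verify to
`1e-8`. Group structure is tested with ANOSIM (Clarke's R, denominator
`n(n-1)/4`) and PERMANOVA, both with 999 permutations by default and
p-values under the `(b+1)/(m+1)` convention so a permutation p is never
zero. Pairwise PERMANOVA post-hoc p-values are Benjamini–Hochberg
adjusted. Cross-platform structure is compared on the PCoA projections
(all positive-eigenvalue axes, truncated to the smaller configuration —
no arbitrary axis cut-off) with symmetric Procrustes `r = sqrt(1 - m²)`
and with the RV co-inertia coefficient; an option computes RV on the raw
clr tables instead. The 6×6 RV matrix across platforms and ranks gets a
unit diagonal, entries clipped to [0, 1], and is eigendecomposed as
`K = U Λ² Uᵀ` with dataset projections `U Λ`; eigenvalues below zero by
more than `1e-8` reject the matrix as indefinite, smaller negatives are
clipped.

**Machine learning.** One stratified split (default: 10 test samples per
diagnosis class) is drawn once and reused for both platforms and all
ranks, so every cross-platform agreement statistic compares predictions
over identical samples. SVMs are one-vs-one ensembles of three binary
linear-kernel models combined by majority vote; a cyclic three-way tie is
broken by the largest summed absolute decision value, then by class order
control < HRL < CRC. Hyperparameters (SVM cost in {0.1, 1, 10, 100}; RF
trees in {500, 1000, 2000}, node size in {2, 3}) are chosen by mean
accuracy over 5 stratified CV folds, ties resolved toward the simpler
model. RF "fitted" training labels are the out-of-bag predictions — the
forest's native fitted values — while SVM fitted labels are training-set
predictions. Importance is mean decrease in node impurity for RF
(permutation importance by flag) and mean absolute hyperplane weight
across the three binary models for SVM, with per-binary rankings also
retained. Signature similarity uses Kendall's tau-b over taxa present in
both models (bootstrap CI over taxa, n = 2000) and top-k overlap with
conventional k of 50 species, 20 genera and 10 families. Accuracy CIs are
percentile bootstrap over test indices; prediction-agreement kappa gets a
normal-approximation CI.

## What the generator emulates — and what it does not

`simulate_paired_study()` draws a latent log-normal community (baseline
log-abundance sd 2 across taxa, per-sample noise sd 0.6) and observes it
twice. The defaults encode the study conditions the pipeline targets:

* 156 samples in three diagnosis groups (51 controls / 54 HRL / 51 CRC);
* mean depths 50,000 (shotgun) and 5,000 (16S) reads — a scaled-down
  10:1 ratio preserving the sparsity ordering while keeping a full run in
  minutes; study-scale depths are a config field away;
* 300 shotgun species in a nested taxonomy (3 species/genus, 4
  genera/family), 10% of them accession-only ("MGYG…");
* 16S detects 60% of the species, plus 15% extra species absent from the
  shotgun catalogue (under their own lineages, mirroring
  database-coverage gaps), with 16S copy numbers uniform in 1–10;
* 20% of detectable 16S species collapse into within-genus slash groups,
  matching the roughly one-fifth ambiguity rate seen in practice;
* genome lengths uniform in 2–8 Mb bias the shotgun counts;
* a `coupling` dial in [0, 1] scales a per-taxon platform bias plus
  per-observation noise (sd 1) by `1 - coupling`, so platform agreement
  degrades continuously as coupling drops (default 0.8);
* 10 signature species get a +1.5 log-scale shift in CRC and half that in
  HRL, encoding the adenoma–carcinoma continuum; the signature is always
  drawn from named, 16S-detectable species so both platforms can see it.

The generator does *not* emulate read-level artifacts (chimeras, host
contamination, primer bias within the 16S gene), strain-level structure,
batch effects between sequencing runs, or database mislabelling. Passing
tests therefore demonstrate that the statistical machinery behaves
correctly under the assumed community model — not that any particular
real dataset will show the same effect sizes.

## Numerical choices and degenerate inputs

* Tolerances: clr rows sum to zero within `1e-9`; distance symmetry
  `1e-12`; PCoA/PCA sign-matched agreement `1e-8`; RV-matrix
  reconstruction `1e-8`.
* Cohen's kappa is reported missing (`NA`) when expected agreement is 1
  (both sequences constant and equal); per-sample statistics that are
  undefined (no shared taxa, constant binarization) are excluded from
  medians and counted in an `n_undefined` tally.
* Ties in taxon orderings (top-prevalent, importance rankings) break
  alphabetically, making reports deterministic.
* Samples with zero total counts are rejected at zero replacement;
  empty filter results and all-unnamed tables warn and return empty
  tables rather than erroring, so pipelines can report the condition.
* All stochastic stages (rarefaction, permutation tests, CV folds,
  forests, bootstraps, the split) consume seeds derived from one master
  seed, recorded in the run manifest.

## Design decisions that were genuinely open

* *Shared-species matching:* ambiguous 16S slash-taxa match shotgun
  species by exact label after harmonization (the conservative default);
  `any_candidate = TRUE` lets any candidate name count as a match, which
  bounds the agreement from above.
* *RV input:* the RV coefficient is computed on PCoA projections (the
  ordinations being compared); a flag accepts raw clr tables instead.
* *Detection:* "detected" means non-zero raw count; zero replacement only
  affects compositional statistics.
* *Alpha correlation headline:* Spearman, with Pearson also reported.
* *Filter evaluation:* relative abundance for the filter is computed on
  genome-length-normalized shotgun proportions.
* *Rarefaction depths* are computed from the data as per-platform minima,
  never hard-coded constants.

## Problem sizes used by the tests

The unit suite runs on small synthetic studies (36–90 samples, 60–150
species). The statistical guarantees are checked at desk scale: oracle
equivalence on 200 random instances per statistic; permutation-test
calibration on 1,000 null communities of 30 samples (99 permutations
each); generator-recovery properties over 20 seeds; and ML concordance on
90-sample studies with 150 species over 20 seeds. The acceptance script
runs the full default study (156 samples, 300 species, three ranks, both
classifiers, 999 permutations, 2,000 bootstraps) in a few minutes on one
CPU.

## Known limitations

* Synonym maps are single-step lookups; resolving multi-step historical
  renames is the user's responsibility (the constructor rejects chains
  rather than collapsing them).
* The kappa CI uses the simple large-sample standard error, adequate for
  sample sizes in the hundreds but approximate for very small tests.
* Procrustes and RV compare linear ordination structure only; nonlinear
  agreement between platforms would need different machinery.
* The generator's multinomial sampling ignores overdispersion beyond the
  lognormal layer; real libraries are often noisier at low depth.
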