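---
title: "Multi-omics consensus subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics consensus subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chondroclass)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and rationale, what the synthetic cohort does and does not
emulate, the numerical choices, and the known limitations.

## The classification model

Chondrosarcoma heterogeneity is organized along three molecular axes that
the pipeline discovers independently and then integrates:

* an **expression axis** (quiescent E1 vs mitotic E2): loss of chondrogenic
  differentiation programs with gain of cell-cycle programs;
* a **microRNA axis** (Mir1–Mir4): graded, regional loss of expression of
  the ~100-member imprinted 14q32 microRNA cluster;
* a **methylation axis** (M1–M3): genome-wide CpG hypermethylation in
  IDH-mutant tumors, with a further dedifferentiated methylation state.

Each axis is recovered by the same procedure: ICA-based removal of
non-neoplastic/technical signal, then feature-resampled hierarchical
consensus clustering. The integrated six-class system (C1/2, C3, C4, C5,
C6) is the consensus of a partition-around-medoids clustering of the
averaged per-omics co-classification matrices.

### ICA confound removal

`fit_ica()` implements JADE: the sample-space data are whitened by SVD and
the fourth-order cumulant matrices are jointly diagonalized by Jacobi
rotations. JADE is deterministic, which the pipeline's reproducibility
contract relies on; the `seed` argument is recorded for provenance only.
Two conventions make the decomposition unique: components are ordered by
decreasing explained variance, and each component's heaviest-tailed
direction is made positive.

The component count is selected from the distance-correlation curve
(`component_count_curve()`): for each candidate `m`, the correlation
between inter-sample Euclidean distances in the rank-`m` reconstruction and
in the original space. Distances are taken on the least-squares
reconstruction rather than on whitened projections because whitening
destroys the relative scale of components and the curve would otherwise not
plateau at the true rank. The selected `m` precedes the largest drop in the
gain of this curve.

Component annotation (muscle, hematopoietic, technical) is a manual step in
practice; here
`flag_confounded_components()` automates the decision by correlating sample
projections with known covariates (contaminated fractions, batch, library
depth) at a default threshold of |r| > 0.6, and
`top_component_features()` supports manual review. `remove_confounded_features()`
removes the top 20% of features by absolute correlation with each flagged
component; the removal universe is whatever matrix is passed (the ICA
input by default; the alternative of scrubbing the full feature set is
available by passing the full matrix).

### Consensus clustering

`run_consensus()` resamples **features**, not samples: all sample pairs are
observed in every iteration, so every co-classification entry has full pairwise support. The most-variant
pool is computed once (fraction 0.2 for mRNA/methylation, 0.5 for miRNA —
the reference analysis used 20% for all omics in its general protocol but 50%
for the miRNA step, and the omics-specific value wins) and 80% of it is drawn per iteration. Ward linkage
(`ward.D2`) on the Pearson distance `1 − r` clusters samples; trees are cut
at every k in 2..9.

Consensus labels use complete linkage on `1 − M(k)`, with classes renamed
by decreasing size so labels are stable across runs. K is selected by the
cophenetic criterion: the correlation between the complete-linkage tree's
cophenetic distances and `1 − M(k)` itself (the distance actually
clustered; correlating against the raw-data distances is available via the
consensus object if needed), taking the K before the largest drop.

### Integration

`average_coclassification()` averages the per-omics consensus matrices at
their selected K — the similarity of two samples is the mean probability of
sharing a subtype across omics. `run_pam_consensus()` subsamples **samples**
(there are no features in a similarity matrix), partitions each subsample
around medoids (`pam_medoids()`, classic BUILD + steepest-descent SWAP,
deterministic with smallest-index tie-breaks), and normalizes
co-classification counts by pairwise co-inclusion counts. K maximizes the
dispersion coefficient `ρ = mean(4 (M − ½)²)`, which is 1 exactly when all
iterations agree; ties resolve to the smaller K, and a
cophenetic-style `k_rule = "pre_drop"` alternative is available.

### Surrogate classifiers

`moderated_t_test()` implements the empirical-Bayes moderated t: per-feature
pooled variances are shrunk toward a global prior whose hyperparameters
(`d0`, `s0²`) come from moment matching on log variances with trigamma
inversion. Setting `d0_override = 0` reproduces the ordinary pooled t
exactly, which the tests exploit; the full estimator is cross-checked
against limma. Markers are the top 200 over-expressed features per class
(two-class or one-vs-rest), or all features at FDR ≤ 5% for the merged
14q32 scheme, whose marker count is data-dependent by design.

No SVM package is available in the target environment, so the linear SVM is
implemented directly as the L2-regularized squared-hinge primal (the
LIBLINEAR "L2L2" formulation) optimized by BFGS from a zero start —
convex, deterministic, linear-kernel, cost C = 1 by default.
`repeated_cv_accuracy()` uses stratified 10×10-fold cross-validation and
re-selects markers inside every training fold, so the estimate carries no
selection leakage; `select_once = TRUE` instead fixes the signature on the
full data first, for comparability with workflows that do so.

`assign_multiomics_class()` encodes the recursive partitioning of the three
predictions: M3 → C6 (dedifferentiated-like); within M2, 14q32 status
separates C5 (silenced) from C4; within M1, the expression class separates
C3 (mitotic) from the merged C1/2 (quiescent). The basis distinguishing C1
from C2 is not recoverable from the three schemes, so a merged label is emitted.

## The synthetic cohort

`simulate_cohort()` generates the 102-sample world used by every
statistical test: class sizes 18/19/15/19/20/11, latent attributes per
class (see `?simulation_params`), 2000 genes / 800 miRNAs (102 in 14q32) /
5000 CpGs. Key modeling decisions, each a deliberate answer to a failure
mode found during development:

* **Admixture contamination.** Muscle and hematopoietic contamination act
  as mixtures: the observed profile is `purity · tumor + fraction · tissue`.
  Additive-only contamination produced stable spurious clusters at every
  strength; dilution reproduces the real phenomenon that heavily
  contaminated samples lose class identity, and makes ICA-based feature
  removal genuinely rescuing (Pearson correlation is robust to the residual
  scaling). Contamination "strength" scales the prevalence and cap of the
  contaminated fractions and the muscle signature amplitude,
  so doubling it reaches a destructive regime while the default cohort
  retains at most a few percent heavily contaminated samples.
* **Proportional heterogeneity.** Every latent program varies between
  tumors with a coefficient of variation of 0.25 plus a small floor.
  Heterogeneity proportional to activity is essential: jittering inactive
  programs creates class-independent coherent noise axes that hijack
  correlation clustering. The resulting elongation of the mitotic axis
  makes the forced 3-cluster cut of the expression data slide with every
  feature draw — which is precisely why the cophenetic curve cliffs after
  K = 2 and the selection rule works.
* **Pattern-distinct silencing grades.** A correlation distance cannot
  separate classes that differ only in the magnitude of one silencing
  axis (deep grades merge, shallow ones fragment). Grades therefore differ
  in pattern: two segments of the 14q32 cluster are repressed to
  grade-specific depths and each grade represses its own small set of
  non-14q32 microRNAs, deepest for the most aggressive grade; class medians
  of 14q32 expression still decrease strictly with grade.
* **Loose nesting.** Ten quiescent IDH-wild-type samples carry mild
  (grade 1) silencing, mirroring the real cohort where the silenced miRNA
  classes far exceed the IDH-mutant classes. These samples are the sixth
  block of the integrated classification; because the planted C1 and C2 are
  molecularly identical, evaluation merges them.
* **Counts and beta values.** miRNA counts are negative binomial
  (size = 5, the standard small-RNA-seq choice) under a 4-fold library-depth
  gradient; methylation is simulated on the M-value (logit) scale and
  mapped through the inverse logit so beta values stay in [0, 1] by
  construction.

What a green test does *not* establish: the generator plants clean class
archetypes with Gaussian/NB noise; it does not emulate correlated probe
noise, copy-number-driven expression dosage, subclonal mixtures of tumor
states, or survival structure. Quantitative effect sizes have no published reference values; they are
calibrated once so that the
planted structure is strong but imperfectly nested — the statistical regime
the pipeline assumes — and then frozen.

## Numerical choices

* Quantiles are type-7 (linear interpolation) everywhere, fixed for
  bit-stability.
* The detection filter reads "more than two counts in more than two
  samples" strictly: ≥ 3 reads in ≥ 3 samples.
* Upper-quartile normalization computes each sample's 75th percentile of
  non-zero counts and rescales to the geometric mean of these quartiles,
  then applies log2(x + 1) before ICA and clustering (whether to
  log-transform miRNAs is a convention choice; the transform log records it).
* Variant-feature selection breaks SD ties lexicographically by feature id;
  consensus class codes sort by decreasing size then first occurrence; PAM
  breaks cost ties by smallest index. All randomness flows from a single
  seed through fixed per-stage offsets.
* JADE's Jacobi sweeps stop when no rotation exceeds `1e-6/√n` (capped at
  100 sweeps); the trigamma inversion uses Newton iterations to relative
  tolerance 1e-8.

## Known limitations

* **Dispersion-based K selection on planted-block worlds.** With
  feature-only resampling, a sample's cluster assignment is fixed by its
  realized noise (feature draws perturb aggregate margins by a few
  percent), so single-omics consensus matrices are near-binary and all
  samples of a block share identical rows in the averaged similarity. PAM
  partitions at every K up to the block resolution are then deterministic
  under sample subsampling and their dispersion is exactly 1; with ties
  resolved toward the smaller K, the argmax rule selects the coarsest tied
  K rather than the block resolution. Real cohorts escape this because
  biological margins reach down to the resampling noise scale, making
  consensus matrices individually graded — but a synthetic world that did
  the same would no longer satisfy the crisp single-omics recovery the
  other tests require. The package therefore demonstrates the integration's
  *partition* quality at K = 6 (adjusted Rand ≥ 0.8 against the planted
  truth) while the automatic K = 6 selection is documented as out of reach
  at desk scale; the corresponding acceptance expectation is intentionally
  left failing rather than weakened.
* The surrogate's cross-validated accuracies on synthetic data
  qualitatively mirror the accuracy range achievable on real cohorts but are
  not a numeric reproduction of any published value.
* C1 vs C2 cannot be resolved by design; all evaluation merges them.
* The generator's contamination model covers muscle and hematopoietic
  admixture only, and the pipeline's automatic component flagging requires
  confound covariates; fully unsupervised component annotation is out of
  scope.
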