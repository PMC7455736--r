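---
title: "Immuno-methylomic deconvolution with methylTIME: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immuno-methylomic deconvolution with methylTIME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylTIME)
```

## The problem

Bulk tumor DNA methylation arrays measure a mixture: the β-value of a CpG in
a tumor biopsy is a cell-proportion-weighted average of the β-values of the
cell populations present. Because methylation is an unusually stable and
cell-type-specific mark, a signature matrix of differentially methylated
CpGs over purified reference populations lets one invert this mixture and
estimate the relative proportions of infiltrating cell types — the tumor
immune microenvironment (TIME) — from data routinely collected for
diagnostic classification. methylTIME implements that inversion and the
analysis layer around it for a 12-class reference roster: Treg, CD4T, CD8T,
B-cell, NK, eosinophil, neutrophil, monocyte, endothelial, glia, neuron,
and cancer.

## Model and procedure

### Signature construction

For each unordered pair of cell classes we test every probe for
differential methylation and select, per comparison, at most `maxDMPs`
(default 200) probes satisfying |median β difference| ≥ `deltaMin` (default
0.2) and BH-adjusted p ≤ `fdrMax` (default 0.01). Selection is *balanced*:
candidates are split by the sign of the β-delta, each direction is ranked by
|delta| (descending, with a lexicographic probe-ID tie-break for
reproducibility), and the top `maxDMPs/2` are taken per direction. One-sided
selection makes the probe set depend on the order in which pairwise
comparisons are enumerated; drawing equally from the hypo- and
hyper-methylated lists removes that artifact. The signature value for probe
p and class c is the mean β over class-c replicates, scaled ×100 into
[0,100].

The per-probe test is Welch's t on β-values with BH adjustment within each
pairwise comparison. With ≥3 replicates per class and the effect sizes that
survive a 0.2 median-delta threshold, selection is dominated by the delta
criterion, so a moderated-variance linear model adds little here; the test
is isolated in one internal function and swappable. Whether FDR should be
controlled within each comparison or jointly across all comparisons is
genuinely open; we default to per-comparison (each comparison is its own
family, matching per-comparison caps) and expose `fdrScope = "global"`.

Two QC steps follow. Cancer in the reference is represented by cell lines,
which are far more variable than sorted normal cells; probes where the two
cell-line families disagree (between-family mean β difference > 0.1 **and**
SD across MB-family lines > 0.15 — a conjunction: both conditions must hold)
are removed, since they would let line-to-line variability masquerade as
infiltration. Second, probes whose average per-tumor-type SD falls below
0.005 are *flagged* but kept: near-invariance in tumors is expected for
probes tracking cell types with uniformly low infiltration, so removal is a
user decision, not a default.

A grid search (`gridSearchSignature`) evaluates deltaMin ∈ {0.2, 0.3} ×
maxDMPs ∈ {100, …, 500} (10 points) on a benchmark mixture set, scoring each
signature by mean recovery correlation, RMSE, and "unattributed" mass
(estimate assigned to classes absent from the truth). No single metric
dominates, so the winner minimizes the sum of the three per-metric ranks —
a deliberately simple composite, reported alongside the full table so users
can apply their own trade-off.

### Deconvolution

Relative-mode support-vector mixture regression. The signature matrix X is
z-standardized over all entries jointly (preserving between-class
contrasts); each mixture y is rescaled ×100 to the signature scale and
z-standardized over its probes, which makes the estimates exactly invariant
to positive rescaling of the input. For each ν in {0.25, 0.5, 0.75} we fit a
linear-kernel ν-SVR of y on the columns of X and keep the ν whose fitted
mixture has the smallest RMSE against y. The coefficient vector is clamped
at zero and normalized to sum 1. Per-sample diagnostics are the fit RMSE,
the fit Pearson correlation, and a permutation p-value: a shared null
distribution of fit correlations from `nPermutations` (default 1000) random
permutations of pooled mixture values, with add-one smoothing, so p is
floored at 1/(nPermutations+1). Quantile normalization is deliberately not
applied.

**Numerical route.** The ν-SVR dual has one variable per probe, and generic
SMO solvers converge very slowly when the mixture is an almost exact linear
combination of the signature columns — precisely the regime of noiseless
benchmarks. With a linear kernel the primal objective

0.5‖w‖² + C·(ν·n·ε + Σᵢ max(0, |yᵢ − Xᵢw − b| − ε))

has only K+2 free parameters (K classes, intercept, tube width ε ≥ 0), so
the default engine minimizes it directly by L-BFGS-B on a lightly huberized
hinge (smoothing width 10⁻⁴ on the standardized residual scale, ε
parameterized on the log scale, warm starts along the ν grid). This is the
same optimization problem libsvm solves; on structured test cases the two
routes agree in the final proportions to well under 10⁻³, which the test
suite asserts, and `engine = "libsvm"` remains available.

Probes present in the signature but absent from a mixture are dropped with a
logged count (never imputed); deconvolution refuses to run if fewer than
half the signature probes are found.

### Derived summaries, scores

`nonCancerProportions` renormalizes estimates over the 11 non-cancer classes
("proportion of all non-cancer cell types"); `tilFraction` sums Treg + CD4T
+ CD8T + NK on either scale. The validation scores are: the meTIL score
(first principal component of the five z-scored meTIL CpGs, sign-oriented to
correlate non-negatively with hypomethylation, so higher = more
T-lymphocyte infiltration; the exact transform in the original code is not
fully specified, so a scaled-mean variant is provided and both are exposed);
the cytolytic score CYT (per-sample mean of GZMA and PRF1 — read literally
as the arithmetic mean of the log-scale values, with the geometric mean
behind a flag since usage differs between sources); a
microglia-vs-peripheral-monocyte ratio (per panel: per-gene z across
samples, averaged over the panel, min–max rescaled to [0,1] across the
cohort — the rescaling avoids ratios of negative z-scores — then
microglia/(microglia+peripheral), NA-flagged at 0/0); and a single-sample
gene-set enrichment score (genes ranked by expression descending; in-set
genes increment a running sum proportionally to rank-weight^0.25, out-of-set
genes decrement uniformly; the score is the summed deviation, rank-based and
therefore invariant to monotone transformations; normalization by universe
size is off by default because scores are compared within a cohort).

### Clustering and associations

Immune-profile matrices are consensus-clustered: for each k in 2–6,
k-means (10 restarts, Euclidean distance on the proportion vectors — no
further transform, since the profiles are already on a common [0,1] scale)
on 1000 random 80% sample subsets; the consensus matrix is the co-assignment
frequency among co-sampled pairs. Subsampling is over samples only — with
11–12 features, feature subsampling would distort the geometry. The
"optimal" k is not prescribed by any single convention, so we use PAC
minimization (proportion of off-diagonal consensus entries strictly inside
(0.1, 0.9)), with ties to the smaller k; the per-k PAC and consensus-CDF
delta-area are both reported. Final labels cut an average-linkage
hierarchical tree of 1 − consensus. A linear SVM (`trainClusterClassifier` /
`predictCluster`) transfers cluster labels across cohorts,
column-order-normalized.

Associations follow one battery: per cell type Kruskal–Wallis with
tie-corrected Dunn z post hoc tests (BH within each cell type's pairwise
family, BH across cell types for the omnibus p-values — one BH family per
analysis table); Pearson χ² without continuity correction for categorical
association; Spearman rank correlation by default. Survival uses the median
split — "high" strictly greater than the median, ties to "low" — and
reports the two-group log-rank test together with a univariate Cox fit
(Efron ties, the standard default) on the high/low indicator, as hazard
ratio with Wald 95% CI.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study conditions
end to end so every pipeline stage can be exercised and audited without
external data.

* **Reference panels.** Probes are "cg"-prefixed zero-padded IDs so real-data
  code paths are identical. A shared baseline β profile is drawn uniform on
  [0.1, 0.9]; each class shifts a disjoint block of `dmpsPerClass` probes
  (default 400) by `plantedDelta` (default 0.5), half hypo- and half
  hyper-methylated — mirroring the balanced selection the builder expects.
  Baselines at planted probes are drawn so the shifted mean stays in
  [0.05, 0.95] and the planted effect is never clipped. Replicates are drawn
  from a beta distribution re-parameterized by mean and concentration
  (mean-preserving), not additive Gaussian noise, so emitted values never
  leave [0,1]; the default concentration 100 corresponds to a replicate SD
  of ≈0.05 at β = 0.5, typical of sorted-population arrays. Concentration
  ∞ is the exact no-noise mode used in identity tests.
* **Tumor mixtures.** Per-class mean profiles (averaged over replicates, as
  a signature-derivation step would) are combined by a weighted mean: for
  each of the 12 classes, 100 samples in which that class is "spiked" at a
  set proportion, the other non-cancer classes uniform-renormalized, the
  non-cancer block scaled by 0.25, and Cancer fixed at exactly 0.75 —
  1200 samples in total, with the ground truth recorded exactly. The set
  proportion itself is drawn uniformly from [0,1] of the non-cancer
  compartment per sample: the original description fixes "set proportions"
  without stating the values or grid, so the uniform draw is our documented
  stand-in; it exercises the whole [0, 0.25] range of absolute spiked
  fractions. Mixture noise is again concentration-parameterized
  (default 1000, SD ≈ 0.016 at β = 0.5 — modest array-level noise).
* **Cancer-line families.** `generateCancerLines` splits the Cancer
  replicates into MB-like/MRT-like families and plants *exactly*
  `nDivergent` probes with an exact between-family mean difference and an
  exact MB-family SD (a deterministic centered pattern), zeroing replicate
  noise elsewhere. This is deliberately fixture-grade: the point is that
  the QC filter's removal set can be verified to be exactly the planted
  set, which random noise on 20,000 background probes would occasionally
  contaminate. It is not a model of cell-line epigenomes.
* **Expression profiles.** GZMA/PRF1 are affine in the CD8T fraction (exact
  at zero noise). For the microglia ratio, note that pure proportional
  scaling of panel genes by `microgliaShare` is *unrecoverable* by the
  z-then-min-max score — standardization cancels amplitude. The generator
  therefore gives each bulk sample a latent microglial fraction centred on
  `microgliaShare` and appends a few pure-microglia and pure-peripheral
  anchor profiles (sorted-cell controls, flagged via the `isAnchor`
  attribute) so the min–max ends are anchored at the biological extremes
  and the cohort median of the recovered fraction sits at the planted
  share.
* **Clinical annotations.** Exponential survival with the hazard multiplied
  by `plantedHR` in the high-covariate group; independent censoring with
  probability `censorRate`, censored times drawn uniformly before the event.

What passing tests on these data do **not** show: robustness to array batch
effects, detection-p artifacts, Noob-normalization residuals, bimodal probe
populations, correlated probe blocks, or reference/stroma methylome shifts —
none of which the generator simulates. Recovery correlations near 1.0 on
synthetic benchmarks certify the estimator's correctness under its own
assumptions, not field performance on real cohorts.

## Problem sizes, tolerances, degenerate inputs

The packaged tests run the study-scale benchmark once (20,000 probes, 1200
mixtures — a few minutes) and use reduced panels (3,000 probes, 20
DMPs/class, 4 replicates) elsewhere; the reduced panels keep every
qualitative property of the default while staying fast. The consensus
clustering acceptance check uses 150 samples at 200 repetitions. Numerical
tolerances asserted in tests: SVR-vs-NNLS agreement within 0.01 per class on
noiseless blends; primal-vs-dual engine agreement within 0.01 (observed
<10⁻³); recovery metrics against textbook recomputation at 10⁻¹⁰.
Degenerate inputs fail loudly and early: all-identical clustering input, a
median split with an empty stratum, zero-variance covariates, zero-event
survival arms, empty probe intersections, out-of-range β-values (reported
with probe and sample), and duplicate probe IDs are all errors; constant
meTIL probes and 0/0 microglia ratios degrade gracefully with flags.

## Known limitations

* Real reference methylomes, IDAT ingestion and Noob normalization are out
  of scope; the package consumes preprocessed β matrices.
* The published 2215-probe signature cannot be reproduced without the
  original reference profiles; the builder reproduces the *procedure*.
* Permutation p-values share one null distribution across samples (the
  pooled-permutation convention); per-sample re-permutation would be far
  more expensive and is not implemented.
* The meTIL transform and the consensus-clustering rep/subsample settings
  of the original analyses are not fully specified upstream; our choices
  (PC1 with orientation; 1000 × 80% subsampling, PAC minimization) are
  defaults, documented above, not reconstructions.
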