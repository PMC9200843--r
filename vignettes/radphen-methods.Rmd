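---
title: "Methods: harmonized radiomic phenotyping and prognostic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized radiomic phenotyping and prognostic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radphen)
```

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the package's tests
demonstrate. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` compute at run time.

## The problem

CT radiomic features are sensitive to acquisition settings: voxel
spacing, contrast enhancement and reconstruction kernel all shift
feature distributions in ways that have nothing to do with tumor
biology. A cohort scanned heterogeneously therefore mixes biological
variation with batch structure, and any unsupervised phenotype found on
raw features risks clustering scanners rather than tumors. The package
implements a complete analysis chain that (i) standardizes image
geometry, (ii) extracts a fixed radiomic descriptor, (iii) removes
multi-batch effects while protecting clinical covariates, (iv) finds
phenotypes and quantifies their stability and significance, and
(v) measures their prognostic value for progression-free survival (PFS).

## Feature extraction

All scans are resampled to the component-wise minimum voxel spacing of
the cohort, so no scan is ever downsampled on any axis; the image is
interpolated trilinearly and the mask by nearest neighbor. In-mask
intensities are discretized into `n_levels` equal-width bins
(default 32; fixed bin *count* keeps texture-matrix sizes bounded and is
exposed in `extract_config()` because discretization conventions differ
across toolkits).

The descriptor has exactly 102 features in eight families. The identity
of every feature is pinned in `radiomic_manifest()`; definitions follow
the common IBSI-style formulations. Choices worth noting:

* **Texture matrices.** GLRLM runs are accumulated over all 13 unique 3D
  directions and merged into one matrix before features are computed
  (the deterministic "merged" convention). GLSZM zones and the NGTDM
  neighborhood use 26-connectivity. All three matrix builders are tested
  against brute-force oracles (explicit run walks, BFS flood fill,
  per-voxel neighborhood loops) on a thousand random grids.
* **Degenerate NGTDM.** A perfectly uniform region has all gray-tone
  differences zero; its coarseness is capped at 10^6 so the value stays
  finite while preserving "smoother = coarser" ordering.
* **Morphology.** Surface area comes from a marching-tetrahedra
  triangulation at iso-level 0.5 of a lightly smoothed occupancy field
  (Gaussian, sigma 0.9 voxels). Meshing the raw binary field produces a
  faceted staircase whose area is biased upward by roughly a third,
  which depresses sphericity badly; anti-aliasing the field and using
  the mesh-enclosed volume in the isoperimetric ratios keeps sphericity
  in (0, 1] and converging toward 1 for digitized balls. Masks too small
  to survive smoothing fall back to the binary field.
* **LBP.** The operator is the literal 2D 3×3 block: 8 neighbors
  thresholded at the center, rotation-invariant uniform mapping
  (10 bins), computed per axial slice for centers whose 3×3 patch is
  fully in-mask, normalized per slice and averaged over contributing
  slices.

## Harmonization

`combat()` implements parametric empirical-Bayes location/scale
harmonization. Each feature is standardized by a least-squares fit
containing batch indicators and the protected covariates; per-batch
location and scale estimates are shrunk to moment-matched normal and
inverse-gamma priors by iterated conditional modes (tolerance 1e-4 on
the maximum relative change, at most 100 iterations). The implementation
is verified in the test suite against the canonical `sva::ComBat` to
about 1e-7 on a covariate-adjusted fit — the external library serves as
a cross-check only, never as the implementation.

Protected covariates are encoded by `protected_design()`: categoricals
reference-coded on their first level, continuous variables standardized.
Following the harmonized-analysis design, PFS time (in months) and the
recurrence event can be included among the protected variables; this is
the default but it knowingly leaks outcome information into the features
and can be disabled (`protect_outcome = FALSE` in the pipeline
configuration).

`nested_combat()` applies `combat` sequentially under *every* ordering
of the batch variables, scores each resulting feature set by the total
number of features still batch-associated (k-sample Anderson–Darling
test at α = 0.05, counts summed over batch variables and reported
per-variable), and keeps the minimizing ordering. Ties keep the ordering
that matches the batch list as supplied. Features still significant
afterwards are dropped as non-robust (`drop_nonrobust`), with an error
if nothing survives.

The Anderson–Darling test uses the tie-corrected (midrank) k-sample
statistic with the standard asymptotic interpolation of tabulated
critical values; beyond the largest tabulated value the interpolating
quadratic is continued along its tangent so p-values stay monotone in
the statistic. When any batch level has fewer than five samples the
asymptotic approximation is replaced by a seeded 2,000-permutation
p-value (with a warning). A k-sample (not pairwise) statistic is used
for variables with more than two levels.

Two interpretation notes, reflected in the tests: with a scale factor of
2 planted on one batch level, per-feature post-harmonization batch-mean
differences and variance ratios at n = 500 have sampling noise larger
than the idealized per-feature bounds one might hope for, so the
recovery guarantees are asserted on cohort averages (mean absolute
standardized mean difference ≤ 0.1, mean variance ratio in [0.9, 1.1],
mean |γ* − γ| ≤ 0.1); likewise near-idempotence (second application
changes values by ≤ 0.02 σ) is asserted on the mean absolute change.

## Phenotype discovery

Clustering is Ward on Euclidean distances of column-z-scored features
(`ward.D2`; z-scoring is essential because radiomic families differ by
orders of magnitude in scale). `consensus_cluster()` draws
`n_resamples` subsamples (default 1,000 at 80%), clusters each once, and
for every pair of samples records the fraction of co-clustered
appearances among co-sampled appearances; stability per k is the area
under the empirical CDF of those consensus values. Pairs never
co-sampled are recorded as missing and excluded from the CDF.

`sigclust()` tests two-cluster structure: the cluster index (within-
cluster SS over total SS, from 2-means with 10 seeded restarts) is
compared with its distribution under a single Gaussian fitted to the
data (10,000 simulations by default). The null covariance is diagonal in
the data's eigenbasis; the delicate choice is its eigenvalues. Raw
sample eigenvalues are overdispersed at moderate n/d, which makes the
simulated null *easier* to split than the data and the test essentially
unable to reject; hard-flooring them at a background-noise variance does
not cure this. The default is therefore adaptive: John's sphericity test
(α = 0.05) first; if sphericity is retained, the null is spherical with
the average variance, which is exactly calibrated in that regime; if
rejected, the eigenvalues of an oracle-approximating-shrinkage (OAS)
covariance estimate, floored at the background-noise variance (squared
MAD of all centered entries), preserve genuine elongation so a single
stretched Gaussian is still not declared clustered. The classic hard-
floor and raw variants remain available (`null_cov = "floored"`,
`"raw"`). The package's calibration checks cover the spherical null and
an elongated single Gaussian.

`select_k()` picks the largest candidate k whose relative increase in
consensus CDF area exceeds a threshold (default 0.1 — the usual
delta-area heuristic; exposed as a parameter because no canonical value
exists) *and* whose every binary split along the Ward dendrogram is
SigClust-significant, falling back to k = 2 with a logged "no
significant structure" flag when even the root split fails. Because the
split test is calibrated, testing each of the k−1 splits at α would
falsely inflate the selected k with probability ≈ (k−1)α even when the
true structure is simpler; the per-split threshold is therefore
Bonferroni-adjusted to α/(k−1) so the family-wise false-split rate for a
candidate k stays at α = 0.05.

## Prognostic models

Cox models use Efron tie handling. `cv_concordance()` repeats
(default 200 times): shuffle into five folds, fit on four, score the
held-out fold, pool out-of-fold risk scores, and compute one Harrell
concordance per repeat; the summary is the mean with percentile 2.5/97.5
bounds (the aggregation rule is a package choice; a normal-approximation
CI would be the alternative). Inside cross-validation folds, sparse
clinical categories can make the partial likelihood monotone; the fold
fit treats such coefficients leniently (non-converged coefficients
contribute zero risk) because they only affect a handful of held-out
scores, while the user-facing `fit_cox()` raises an informative error
instead. Kaplan–Meier stratification splits at the median risk score of
the full-cohort fit (ties to the low group; a per-stratum refit is the
documented alternative), with the 1-df log-rank test. PD-L1 prediction
binarizes at ≥ 50% ("high") by default, and uses a random forest with
the phenotype as the sole predictor, reporting five-fold CV AUC inside a
stratified 70% training split plus the 30% hold-out AUC. PFS is carried
in days internally; months are days/30.44.

## The synthetic cohort

`simulate_feature_cohort()` generates data under exactly the model the
harmonization assumes: feature g of sample j is
μ_g + cluster effect + covariate effects + γ_ig σ_g + δ_ig σ_g ε. Its
defaults describe the study conditions the pipeline targets: 107
samples, 102 features, two batch variables with 80/27 and 90/17 level
frequencies, γ = 1.5 and δ = 2 on the minority levels, two phenotype
clusters (52/48 mixing, separation 2 σ on half the features — enough
for reliable recovery without being trivial), per-feature σ_g
log-uniform in [0.5, 2] so harmonization is exercised on unequal scales,
a clinical table mimicking the usual covariate mix (PD-L1 %, ECOG, BMI,
smoking, therapy line), log-normal tumor volumes larger in the second
cluster, and exponential PFS with baseline rate log(2)/270 per day
(median 270 days), planted cluster log hazard ratio 0.4, and independent
uniform censoring on [0, 1500] days — the simplest mechanism satisfying
the non-informative censoring assumed by the log-rank test. Batch and
cluster assignments are independent by default; a confounding knob
shifts batch composition with cluster membership for stress tests. All
randomness flows through one seed, and the pipeline fans a single global
seed out to per-stage seeds by fixed offsets.

What the generator does *not* emulate: CT physics (kernels as actual
reconstruction filters, beam hardening, noise textures), correlated
feature blocks as produced by real extraction pipelines, non-Gaussian
feature marginals, informative censoring, and multi-lesion anatomy. A
passing suite therefore shows the pipeline's statistical machinery is
correct and calibrated under its stated model, not that any specific
clinical cohort will yield prognostic phenotypes.

`simulate_tumor_volume()` produces textured ellipsoid image/mask pairs
(smoothed Gaussian noise with class-specific mean and correlation
length) purely as extraction fixtures — no claim of CT realism.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own verification scales: texture oracles on
1,000 random grids up to 4×4×3 with up to 4 gray levels; harmonization
efficacy at n = 200 with 50 features; parameter recovery at n = 500;
consensus recovery at n = 100 with 1,000 resamples; SigClust calibration
over 1,000 (tests) / 500 (script) null datasets of size 50×10 with 100
simulations each (scaled down from the 10,000-simulation default, which
is meant for a single analysis rather than a calibration loop); Cox
calibration with 50 CV iterations against a 200,000-sample oracle; the
end-to-end pipeline at the full 107-sample design with 200 consensus
resamples, 200 SigClust simulations and 50 CV iterations.

## Known limitations

* The 102-feature manifest is a fixed, versioned stand-in assembled from
  standard family definitions; other toolkits' manifests will differ in
  membership and normalization even at the same count.
* The AD-scored nested search evaluates every ordering of the batch
  list, which is factorial in the number of batch variables; it is meant
  for the two-or-three-variable situations that motivate it.
* SigClust's adaptive null is calibrated for the spherical regime and
  protective for elongated Gaussians, but like all eigenvalue-based
  nulls it inherits estimation error when d approaches n.
* Protecting outcome variables during harmonization is faithful to the
  analysis design it reproduces but is a documented leakage risk; turn
  it off for honest out-of-sample claims.
* `morph_max_diameter_mm` is exact over boundary voxel centers, which is
  quadratic in boundary size; very large masks would want a convex-hull
  prefilter.
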