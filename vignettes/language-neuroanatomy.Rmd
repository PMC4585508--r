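---
title: "Methods: morphometry and language individual differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry and language individual differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(langmorph)
```

# The scientific problem

Autism is behaviorally heterogeneous, and one plausible axis of that
heterogeneity is language: whether language emerged late in development
(first single words after 24 months, or first phrases after 33 months), and
how strong structural language ability is in adulthood. `langmorph`
implements the analysis machinery needed to ask whether these two axes are
reflected in structural brain anatomy measured with voxel-based
morphometry (VBM): group contrasts of tissue-volume maps, a commonality
statistic for pairs of contrast maps, a multivariate brain–behavior
decomposition, region-of-interest replication tests, and effect sizes
computable from printed summary tables. Because the MRI cohorts such
analyses are developed on are not publicly shareable, the package also
contains a first-class synthetic cohort generator that reproduces the
statistical structure the analyses assume, so every stage can be exercised
and calibrated without any data download.

# Volume preparation

The inputs are modulated tissue-probability maps in a common template
space: voxel values integrate to local tissue volume, so summing a map and
multiplying by the voxel volume yields the total tissue volume in cm³
(`total_tissue_volume()`). Analyses are restricted to voxels whose
template tissue probability is **strictly** greater than 0.25
(`build_mask()`), avoiding edge effects between tissue classes. Each map
is divided by the subject's own total tissue volume
(`scale_to_relative()`), giving *relative* regional volume; this
individual-level adjustment sidesteps the collinearity that arises when a
global covariate correlates with the predictor of interest. By
construction a relative map integrates to exactly 1, which the tests use
as a conservation property.

Age standardization (`standardize_by_age()`) is linear residualization per
voxel with the cross-subject mean restored. Two choices were genuinely
open here. First, "standardized by age" could include scaling by the
residual SD; we keep the residual scale (means restored, no division), so
that voxel units remain interpretable and the operation is idempotent.
Second, voxel indexing: we use R's native 1-based indices throughout and
apply the NIfTI affine to zero-based offsets internally, so MNI mm
coordinates round-trip exactly with external NIfTI tools.

# Voxel-wise GLM and cluster inference

`fit_voxelwise_glm()` fits ordinary least squares at every masked voxel
with a design of intercept, binary group indicator, age (continuous) and
scanning center (reference-coded dummies), and forms
`t = c'β̂ / SE(c'β̂)` on `n − p` degrees of freedom. Voxels with
numerically zero residual variance are reported as `t = 0` rather than a
ratio of rounding errors. The oracle property tested: the map agrees with
an independent `lm()` fit per voxel to 1e-8.

Clusters are formed at a one-tailed height threshold of `P < 0.025` under
18-neighbour connectivity (faces + edges, the convention of the major VBM
packages). Cluster-level inference is by permutation: group labels are
permuted **within scanning-center strata** (center is a fixed-effect
nuisance, so exchangeability should respect it), the GLM and clustering
are recomputed, and each cluster's p-value is the fraction of permutations
whose *maximum* cluster extent reaches that cluster's extent. The identity
permutation is included, so the smallest attainable p is `1/n_perm`.
Benjamini–Hochberg across the detected clusters then controls FDR at
`q < 0.05`. We deliberately do not re-implement Gaussian-random-field
topological FDR with nonstationarity correction: the permutation null is
assumption-light, exactly matched to the design (including strata), and
desk-testable. The thresholds (height `P < 0.025`, cluster `q < 0.05`) are
retained. Under the global null this procedure is conservative — the
maximum-extent null plus BH yields a family error well below the nominal
0.05 (the calibration suite bounds it at 0.08 over 200 synthetic null
cohorts of 10+10 subjects on 16³ grids with 300 permutations each) — which
is the safe side of the trade.

A technical note on speed: the permutation loop uses the Frisch–Waugh
identity (data and the permuted group indicator are residualized against
the nuisance block once), and connected components of small suprathreshold
sets are found by union-find on pairwise voxel adjacency rather than
whole-grid label propagation.

# Overlap commonality

To ask whether two group-difference maps (e.g., each autism subgroup
contrasted against the same neurotypical reference) implicate *common*
anatomy, both maps are thresholded at the same one-tailed voxel-level p
and the conjunction (logical AND) overlap is expressed as a percentage:
the intersection as a proportion of each map's suprathreshold count,
averaged over the two maps. An empty suprathreshold set makes the overlap
*missing*, never zero — zero would fabricate evidence of disparity.

Significance comes from a Monte-Carlo null: pairs of independent Gaussian
random fields with the same spatial smoothness as the observed maps,
standardized on the mask, thresholded identically, their overlap recorded
(reference protocol 5000 iterations; the test suite runs 200–1000). The
p-value is the plain counting probability (`#{null ≥ observed}/n`); a
protected `(k+1)/(n+1)` variant is available via `protected = TRUE`, but
the plain rule is the default for fidelity to the established protocol.
The sweep runs across voxel-level thresholds (reference grid 0.05 down to
0.0001 in steps of 0.0001) with the null's 0.5/50/99.5 percentiles
reported per level. Both contrast directions are analyzed separately.

Smoothness is estimated with a gradient-variance estimator: on the
standardized map, the variance of first differences along axis *k*
satisfies `varΔ = 2(1 − exp(−1/(4σ²)))` for a Gaussian autocorrelation
with σ in voxels, inverting to
`FWHM_k = voxel_k · sqrt(−2 ln 2 / ln(1 − varΔ/2))`. Only difference pairs
fully inside the mask contribute. This estimator is exact for the
generator's fields (periodic Gaussian convolution) and recovers an 8-mm
FWHM within 10% on a 64³ grid; for *unsmoothed* noise it correctly
degenerates toward zero rather than returning a one-voxel floor. Whether
the original protocol standardized its simulated maps before thresholding
is unstated; we standardize, since p-value thresholds presuppose a
calibrated scale.

# Behavioral PLS

Behavioral PLS finds paired brain/behavior latent variables (LVs) by
singular value decomposition of a stacked correlation matrix: for each
block — one per condition (GM, WM) and group — the Pearson correlation of
each behavioral measure (VIQ, F-A-S, non-word repetition) with each masked
voxel across subjects, stacked row-wise. Correlation implies z-scoring
within block, which `cor()` performs implicitly; zero-variance voxels get
correlation 0 with a logged count. LVs are ordered by singular value, and
LV *i* explains `λᵢ²/Σλ²` of the brain–behavior covariance. Brain scores
are the projection of each subject's (centred) voxel data onto the brain
saliences, per condition.

Inference is by permutation of the behavior rows (within group in the
multi-group variant — the established choice when group structure is part
of the model, flagged in the configuration), comparing singular values *by
rank position* (the dominant published practice). Reliability is by
bootstrap: subjects resampled with replacement within group, each
resample's saliences **sign-aligned** to the original per LV (reflection
is unidentified in SVD; without alignment the SEs are corrupted),
degenerate resamples redrawn. The bootstrap ratio is the original salience
divided by its bootstrap SE; `|BR| > 2.5` with a 400-voxel minimum cluster
is a *visualization* convention only — inference rests on the permutation
test.

With GM and WM entering as two conditions over a shared voxel register,
the two tissue blocks share one brain-salience vector per LV. If a latent
factor is expressed in spatially disjoint GM and WM patterns, the stack is
rank-2 and the leading LV concentrates on the stronger block; this is a
property of the method, not an artifact, and the parameter-recovery suite
therefore embeds its "one LV" in a single tissue.

# ROI machinery and effect sizes

Sphere ROIs use a closed ball on voxel centres (membership: Euclidean mm
distance ≤ radius, default 6 mm); the convention of the original toolboxes
is undocumented, so we fix and document this one. Mean regional volume per
subject feeds pooled-variance t-tests; a MANCOVA over a set of language
ROIs residualizes age and center out and computes the Hotelling–Lawley
trace `tr(H E⁻¹)` with the conventional F approximation (for a two-level
group this is Hotelling's T² with `F = T(ve−p+1)/p`). The bundled list of
13 canonical language-region centroids is a **synthetic stand-in**
(marked in its filename) for an external parcellation that is not
redistributable; it exercises the machinery and must not be used for
anatomical inference.

Summary-statistic effect sizes use the pooled-SD Cohen's d (no
small-sample correction — this convention reproduces every printed
parametric value in the bundled reference table to 2 decimals), the pooled
two-sample t, and for Mann–Whitney rows the conversion
`z = (U − n₁n₂/2)/sqrt(n₁n₂(N+1)/12)`, `r = |z|/√N`, `d = 2r/√(1−r²)`.
The "Pearson's r" in such conversions is ambiguous between `z/√N` and the
rank-biserial r; `z/√N` reproduces the printed value and is the default.
A tie-corrected U variance is available behind an argument. Rows of the
bundled table with reduced n (missing data) have no printed group split;
the bundled splits are plausible reconstructions, and the recomputed d is
insensitive to the choice (the printed t is reproduced to 2 dp only for
full-n rows).

# The synthetic cohort generator

`generate_cohort()` draws, per subject: a smooth ellipsoidal tissue
template scaled by a global factor (a fractional total-GM offset of 0.05
for the delay subgroup, mirroring the observed ~5% larger absolute total
GM; an age slope of −0.002/year; additive center offsets of ±2%), plus
additive group-difference blobs (Gaussian profiles, σ = radius/2), plus a
latent language factor expressed spatially (default: a distributed
bilateral temporal GM pattern and a frontal WM component), plus Gaussian
noise smoothed to the 4-mm FWHM of the reference preprocessing
(`FWHM = 2.3548σ`, periodic convolution so the true autocorrelation is
known exactly — this gives the smoothness estimator a ground truth). Maps
are clipped nonnegative. Behavioral scores live on the instruments'
scales (VIQ ≈ 108.7 ± 14.3, F-A-S ≈ 37.7 ± 11.4, NWR ≈ 21.5 ± 4.2) and
follow `score = mean + sd·(λ·factor + sqrt(1−λ²)·noise)` with default
loadings 0.6/0.6/0.5 and a latent-factor group shift of ∓0.3 (delay lower),
which reproduces the medium behavioral effect sizes of the reference
cohort. Developmental milestones are drawn consistently with the delay
rule and `classify_delay()` recovers the labels exactly.

Default geometry is a 32³ grid of 6-mm voxels (±93 mm, so MNI-scale ROI
coordinates fall inside the volume). What the generator does *not*
emulate: scanner physics, segmentation error, registration distortion,
non-Gaussian score distributions, and realistic anatomical covariance
between regions. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under its assumptions — not that any
particular anatomical finding would replicate in real cohorts.

# Problem sizes and numerical choices

The verification suites run at deliberately chosen scales:

* PLS parameter recovery: one cohort of n = 80, 21³ grid (~4200 masked
  voxels), one GM-embedded LV (two blobs of 30-mm radius, amplitude 0.12
  against voxel noise SD 0.05, loadings 0.6); LV1 salience–pattern
  correlation ≥ 0.8 and permutation p ≤ 0.05 at 500 permutations. Null
  calibration: 200 cohorts of n = 20 at 10³, 300 permutations each, LV1 p
  uniform by Kolmogorov–Smirnov.
* Overlap: calibration over 100 independent map pairs (16³, 4-mm voxels,
  200-iteration nulls each); power on one 64³ cohort (3-mm voxels,
  20+20+20 subjects, two shared blobs) with a 1000-iteration null.
* Cluster inference: 200 null cohorts (16³, 10+10) × 300 permutations.
* Reference protocol scales (5000 overlap iterations, 10,000 permutations
  and bootstraps, the 500-level threshold sweep) are the `"paper"` profile
  of `run_config()`; the `"test"` profile scales iteration counts down and
  never touches a threshold.

Numerical conventions worth knowing: strict inequalities at both the mask
threshold and all p-value thresholds; cluster tables sorted by extent with
ties sharing p and q; permutation and bootstrap p-values by plain counting
(protected variants optional); empty-set overlap is missing, not 0;
all randomness in a pipeline run flows from a single seed.

# Known limitations

* The permutation cluster null is exchangeable only within center strata;
  designs with continuous confounders beyond age would need a
  Freedman–Lane scheme, which is not implemented.
* The overlap null assumes stationary, Gaussian, independent fields;
  observed t-maps sharing a reference group violate independence, which is
  why the calibration suite uses disjoint cohorts.
* Bootstrap alignment is sign-only; full Procrustes alignment across LVs
  is not implemented and near-degenerate singular values will inflate SEs.
* The generator's ellipsoidal template is a geometric idealization; mask
  geometry effects (e.g., gyral topology) on cluster extents are not
  represented.
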