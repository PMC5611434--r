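---
title: "Anterior–posterior parcellation of hippocampal subfield masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anterior–posterior parcellation of hippocampal subfield masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subaxis)
library(dplyr)
```

## The problem

Alzheimer-type pathology does not affect the hippocampus uniformly: the
posterior hippocampus, which supports episodic and spatial memory, appears
selectively vulnerable in the pre-dementia stages. A whole-subfield volume
averages away that gradient. `subaxis` implements the analysis strategy of
dividing a single subfield mask (a FreeSurfer-style probability map of the
subiculum) into ten equal-length volumetric segments along its
anterior–posterior axis, and relating per-segment volumes to cerebrospinal
fluid (CSF) biomarkers of amyloid-β and tau pathology and to delayed-recall
memory performance.

Because the clinical cohort this design comes from is not publicly
available, the package carries a first-class synthetic layer: tube phantoms
with known geometry for the image-processing stages, and a cohort generator
whose parameters are fixed to the published summary distributions, so that
every stage of the pipeline is testable end to end.

## The parcellation procedure

1. **Binarization.** The subfield probability map stores membership
   intensities 0–255. A voxel belongs to the mask when its intensity is at
   or above 127. The comparison is inclusive: 127/255 ≈ 0.498 is the integer
   intensity corresponding to membership probability one half, and the
   procedure is defined as "probability 0.5 or higher", so a strict
   comparison would exclude the boundary intensity itself.
2. **Axis.** Among the mask's *surface* voxels (6-connectivity: at least
   one face neighbor missing), the pair with the greatest Euclidean
   distance between voxel centers defines the axis. Restricting the search
   to surface voxels is lossless — an interior voxel lies inside the
   octahedral hull of its six face neighbors and cannot attain the maximum
   — and the test suite verifies equality with an all-voxel brute force.
   The search itself is the exhaustive O(n²) scan; it is the reference
   implementation, and at the mask sizes involved (10³–10⁴ surface voxels)
   it runs in well under a second.
3. **Orientation.** The endpoint with the smaller anterior world coordinate
   is the posterior end. All geometry is computed on voxel *centers* mapped
   through the NIfTI affine into world millimetres, so the procedure is
   independent of storage order and correct for anisotropic voxels; in
   NIfTI world space (RAS) the anterior axis is always world axis 2.
4. **Projection binning.** Each voxel center projects onto the axis at
   normalized position `t`; segment labels are `min(floor(10·t) + 1, 10)`,
   i.e. half-open bins with `t = 1` assigned to segment 10 and segment 1
   most posterior. When the axis is the mask's own diameter every `t` lies
   in [0, 1] up to floating point (a clamp larger than 1e-9 of the axis
   length is treated as an error); this is asserted, not assumed.
5. **Volumes.** Segment volume is voxel count × voxel volume. Empty
   segments are retained as zeros, so segment volumes always sum exactly to
   the mask volume.

Given the ~47%/53% head/body proportion of the hippocampal long axis,
segments 1–5 fall in the hippocampal body, segment 6 straddles the
body–head transition, and segments 7–10 lie in the head;
`map_segment_to_region()` encodes exactly this rule.

### Numerical choices and tie-breaking

Two candidate diameters can tie exactly (voxel centers sit on a lattice).
Ties are resolved by comparing the candidate pairs lexicographically in
*world coordinates*, each pair ordered internally first. A tie rule based on
stored voxel indices would be equally deterministic but would break the
requirement that segment volumes be invariant under the 48 axis
permutations/flips of the stored grid; the world-space rule satisfies both,
and the suite checks all 48 symmetries. If the two axis endpoints tie on the
anterior coordinate (anatomically implausible, but possible for synthetic
input) the lexicographically smaller point is taken as posterior, with a
warning.

## Quality control

Per (hemisphere, segment) cell, volumes more than 3 SD from the cell mean
are set missing (never imputed) in a single pass over the whole sample;
re-running on the filtered table could flag more records and is deliberately
not done. Pooling over the whole sample rather than per diagnostic group is
the simplest consistent reading of the source procedure and is the default.
Under Gaussian data the expected exclusion fraction is 2·(1−Φ(3)) ≈ 0.27%;
heavier-tailed real data can exceed this (the original cohort showed 0.84%).
Downstream models use listwise deletion within each model.

## Biomarker rules

* **Amyloid-β 42.** CSF Aβ42 is bimodal, so the cutoff is estimated from
  the data: a two-component Gaussian mixture (unequal variances) fitted by
  EM, best of 10 quantile-seeded restarts, with a variance floor of 1e-4 of
  the sample variance and a per-iteration assertion that the log-likelihood
  never decreases. The reported cutoff is the *equal-posterior point* — the
  root of `w_a·φ(x; μ_a, σ_a) = w_n·φ(x; μ_n, σ_n)` between the two means,
  found by bracketed root-finding. The equal-density intersection is an
  alternative convention; for well-separated CSF components the two differ
  by a few ng/l. Values at or below the cutoff (527 ng/l in the reference
  mixture) are amyloid-positive.
* **P-tau.** Fixed cutoffs: elevated when strictly above 52 ng/l (default)
  or 70 ng/l (supported alternative).
* **Memory.** Delayed-recall errors on a 10-word list, binned 0–1 / 2–3 /
  4–5 / 6–10.

## The repeated-measures model

`rm_glm()` implements the split-plot ("GLM repeated measures") analysis the
major commercial packages produce, directly on matrices:

* between-subject factors are effect-coded (sum to zero), covariates
  centered, sums of squares Type III — implemented as drop-term residual-SS
  comparisons, which coincide with the commercial Type III for the
  main-effects-only between designs used here;
* the within-subject factor (10 segments, or 2 locations) enters through
  k−1 orthonormal polynomial contrasts; for each between term the
  interaction pools its Type III SS over the contrast columns, giving
  `df_num = df_term·(k−1)` and `df_den = (n−p)·(k−1)` — with 10 segments
  the familiar `F(9, 9·(n−p))` shape;
* between-subject main effects are tested on subject means;
* the uncorrected univariate F is primary; Greenhouse–Geisser ε is computed
  and reported alongside, since the reference analyses report uncorrected
  degrees of freedom. Significance is declared at p < 0.050.

With k = 2 and a single two-level factor the interaction F reduces
algebraically to the squared two-sample t on within-subject difference
scores; the suite uses this, plus an independent Type III ANCOVA on subject
means, as oracles. Calibration is checked by simulation: under a spherical
null (n = 200, k = 10, 2000 replicates) the interaction's type-I error must
stay within [0.035, 0.065] at α = 0.05, and a 0.5 SD posterior-only atrophy
(segments 1–5, n = 150/group, 500 replicates) must be detected with ≥80%
power. These replicate counts keep the simulations to a few minutes on one
core while leaving the Monte-Carlo error well inside the asserted bands.

Pairwise post hocs compare covariate-adjusted cell means per within level
with the pooled residual error of that level's model; Bonferroni multiplies
raw p by the number of comparisons (capped at 1), Fisher's LSD leaves them
unadjusted. Partial correlations residualize both variables on the
covariates by least squares; p-values use `t = r·√(df/(1−r²))` with
`df = n − 2 − q`.

No correction is applied *across* the ten segment-wise contrasts — the
reference analyses report per-segment p-values uncorrected, and the package
reproduces that convention.

## What the synthetic cohort emulates

The calibration-mode generator draws independent standardized drivers
A (age), P (P-tau), M (memory), I (head size) and noise Z, and builds the
per-side total volume as

V = μ_V + σ_V·(−a·A − p·P − q·M + β·I + e·Z),

with a = 0.34, p = 0.1693, β = 0.20 and e chosen so the loadings
square-sum to 1. Age is 72.2 (5.5) years; P-tau is 58 (24) ng/l with the
driver rejection-sampled so concentrations stay non-negative; ICV is
1.45e6 (1.5e5) mm³; memory errors are `round(clip(3.6 + 2.8·M, 0, 10))`.
Because rounding and clipping attenuate the latent correlation by
κ = cor(M, errors) ≈ 0.9774 (estimated once from a 100,000-draw pilot,
`calibrate_memory_loading()`), the memory loading is inflated to
q = 0.41/κ = 0.4195 so the *observed* error–volume correlation is −0.41.
The right hemisphere uses the same construction with the memory loading
scaled to target −0.36, reflecting the left-dominant asymmetry reported in
the literature (the asymmetry's mechanism is not modeled). Aβ42 is drawn
independently of volume from 0.393·N(395, 78²) + 0.607·N(762, 150²), whose
analytic equal-posterior point is 527.45 ng/l — verified by root-finding,
so no component adjustment was needed.

Total volume is spread over 10 segments with a fixed near-uniform base
profile; the P-tau and memory channels are loaded with posterior weights
w_s ∝ (11 − s), so their correlations attenuate monotonically from
posterior to anterior — the structural analog of the posterior-dominant
findings. Per-segment iid noise (sd 4 mm³) attenuates total-volume
correlations by a factor 80/√(80² + 10·4²) ≈ 0.988, which the calibration
tests account for. The per-side volume scale μ_V = 500 mm³, σ_V = 80 mm³
is an invented default: subfield totals are not published, only
whole-hippocampus volumes, so the scale is arbitrary and only relative
effects matter.

Study-like mode adds CN/SCD/MCI structure — group-specific age, P-tau and
memory distributions, group amyloid-positivity rates (82/302, 69/183,
107/171) with Aβ42 drawn from the matching mixture component, and a
posterior-only volume reduction (0.5 per-segment SD on segments 1–5) in
biomarker-abnormal participants. It demonstrates the full pipeline and
powers the power simulations; it is *not* used for numeric calibration.

What the synthetic layer does **not** emulate: realistic subfield shape
(tubes stand in for the subiculum's curved sheet), segmentation error,
spatial autocorrelation between neighboring segments beyond the shared
channels, non-Gaussian biomarker tails, and any longitudinal structure.
Passing tests therefore certify the algorithmic and statistical machinery,
not neuroanatomical validity on real data.

## Known limitations

* The straight farthest-pair axis is a chord; for strongly curved masks
  (chord/arc < 0.8) projection binning compresses the curved middle, and
  no geodesic alternative is provided (out of scope by design).
* The equal-posterior mixture cutoff at n ≈ 656 has a sampling SD of
  roughly 16 ng/l for CSF-like component overlap — single-cohort cutoffs
  should be reported with that uncertainty in mind. This spread is a
  property of the estimation problem: an independent maximum-likelihood
  mixture fit shows the same distribution.
* Excluded QC records are dropped listwise per model; no imputation or
  robust alternatives are offered.
* The split-plot F is reported unadjusted for sphericity (matching the
  reference convention); for strongly non-spherical data users should
  consult the reported Greenhouse–Geisser ε.

## Reproducing the pipeline

```{r, eval = FALSE}
cohort <- generate_cohort(n = 656, seed = 1,
                          config = cohort_config(mode = "study_like"))
qc     <- flag_outlier_segments(cohort, z_threshold = 3)
report <- run_full_analysis(qc$cohort, abeta_cutoff = 527, ptau_cutoff = 52)
tidy(report$abeta_segments$left)
autoplot(report$abeta_segments$left)
```

The acceptance script (`scripts/acceptance.R`) regenerates a
calibration-mode cohort from a seed and recomputes the four headline
quantities (age–volume correlation, P-tau partial correlation, memory
correlation, mixture cutoff) from scratch.
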