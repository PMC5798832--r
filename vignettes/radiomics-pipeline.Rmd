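---
title: "Methods: 3D nodule radiomics and signature building"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D nodule radiomics and signature building}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctradiomics` implements a complete lung-nodule radiomics workflow: a
750-feature 3D extractor operating on a CT volume plus an expert-drawn
binary region of interest (ROI), and the statistical machinery that turns a
cases-by-features table into a small diagnostic signature for
benign/malignant classification. This vignette explains the model choices,
the tunable parameters, what the synthetic phantoms do and do not emulate,
and the numerical conventions at degenerate inputs.

## The feature model

Every feature is computed strictly from in-mask voxels. Out-of-mask voxels
inside the bounding box are sentinels: voxel pairs, runs, zones and
neighbourhoods never bridge them, and before any convolution they are
infilled with nearby in-mask values so that background air cannot leak into
texture statistics.

The inventory has nine blocks (750 features in the default configuration):

| block | count | content |
|---|---|---|
| intensity & shape | 33 | 16 summary statistics of the raw intensities, 10 intensity-volume histogram features, 7 mask morphology features |
| LoG | 96 | 16 statistics × 6 Laplacian-of-Gaussian scales (1–6 mm) |
| wavelet | 128 | 16 statistics × 8 one-level 3D Haar subbands |
| Laws | 432 | 16 statistics × 27 separable Laws kernels |
| co-occurrence | 26 | descriptors of the 13-direction GLCM at 256 levels |
| run-length | 11 | Galloway descriptors of the 13-direction RLM at 256 levels |
| size-zone | 11 | size-zone analogues over 26-connected zones (64 levels) |
| gray-tone difference | 5 | Amadasun–King regional descriptors (64 levels) |
| fractal | 8 | box-counting dimensions of range-fraction thresholded sets |

**The shared 16-statistic set.** Each filter response (and the raw ROI) is
summarised by: min, max, median, histogram peak, mean, SD, coefficient of
variation, RMS, skewness, excess kurtosis, energy (unnormalised sum of
squares; RMS carries the normalised version), histogram entropy (base-2, 64
bins over the observed range), uniformity, range, and a co-occurrence
contrast/homogeneity pair computed on the response re-quantised to 32
levels. The last pair means the statistic set itself is texture-aware, so a
"Laws_ESE_contrast" is the co-occurrence contrast *of the Laws ESE
response*. The set is fixed at these 16 names so that 27 × 16 = 432,
8 × 16 = 128 and 6 × 16 = 96 reproduce the block totals above.

**Laws kernels.** The length-3 family L3 = (1,2,1), E3 = (−1,0,1),
S3 = (−1,2,−1) (level/edge/spot), combined by outer product into 27
separable 3D kernels; letter *k* of the id acts along axis *k*. The
3-letter ids over exactly {L,E,S} are the only family consistent with 27
kernels and the 432-feature block. Borders are mirror-padded.

**Wavelet.** One-level separable 3D discrete wavelet decomposition with the
orthonormal Haar filter (chosen for exact arithmetic in tests; the gain of
the scaling filter is √2 per axis). Subband coefficient grids are mapped
back to the patch geometry by nearest-coefficient upsampling so the ROI
mask applies unchanged.

**LoG.** The Laplacian of a 3D Gaussian, computed in physical units as the
sum of three separable second-derivative terms, with scales σ ∈ {1,…,6} mm
— six scales from fine to coarse blob structure, the only cardinality
consistent with the 96-feature block. Kernels are sampled to 3σ and
corrected to zero sum, so constants and affine ramps respond exactly zero.

**Gray-level discretisation.** Equal-width binning over the in-mask
min–max range (the common convention when no fixed calibration window is
assumed). GLCM and RLM use 256 levels; size-zone and gray-tone difference
matrices default to 64 levels, which keeps those matrices dense enough to
be informative on nodules of a few thousand voxels. All four are knobs in
`radiomics_config()`.

**Directions.** The 13 unique non-antipodal offsets with components in
{−1,0,1} at distance one voxel. GLCM counts are symmetrised, summed over
directions and normalised; RLM run counts are summed over directions and
normalised by total run count.

**Intensity-volume histogram.** I*x* is the largest intensity covering at
least *x*% of the ROI volume at or above it; V*x* is the volume fraction at
or above the intensity *x*% of the way from the in-mask minimum to the
maximum (min–max anchoring keeps the definition meaningful for negative
Hounsfield values). Both use the decile grid {10,30,50,70,90}, giving the
10 features that complete the 33-feature block.

**Shape.** Volume is voxel count × voxel volume. Surface area is estimated
mesh-free via the coarea formula — the mask indicator is smoothed with a
half-voxel Gaussian and the gradient magnitude integrated over the volume.
The half-voxel scale was calibrated against analytic sphere areas: it is
accurate to a few percent and errs on the overestimate side for digitised
convex bodies, so that sphericity π^⅓(6V)^⅔/A respects its upper bound of
1; a residual cap at 1 guards the remaining discretisation noise, and
compactness2 is reported as sphericity³ so the algebraic identity between
the two is exact. Maximum diameter is the largest pairwise distance
between surface voxel centres.

**Fractal block.** The in-mask intensities are thresholded at eight
fractions (10%–80%) of their range; each binary set gets a box-counting
dimension from a least-squares fit of log N(ε) against log(1/ε) over box
sizes {2,4,8,16} voxels. An empty set has dimension 0 by convention. The
eight thresholds match the eight-feature block total; the construction is
a local convention documented in the feature registry.

## Degenerate-input conventions

All 750 features are finite on any valid ROI, including a constant one:

* zero-variance samples: skewness = kurtosis = 0, entropy = 0,
  uniformity = 1; coefficient of variation is 0 when the mean is 0;
* a patch with no valid voxel pair: co-occurrence contrast 0,
  homogeneity 1 (the constant-image limit);
* co-occurrence correlation of a zero-variance matrix is 1; information
  measures fall back to 0 when a marginal entropy vanishes;
* gray-tone difference coarseness is guarded by ε = 10⁻⁶ and capped at
  10⁶; busyness and strength are 0 in the same limit.

## The statistical back half

The pipeline follows the classical order: quantile normalization across
all cases → two-sided Wilcoxon rank-sum screening at α = 0.05 with no
multiple-testing correction → sequential forward selection (SFS) of k = 4
features wrapped around a linear SVM (cost 1) evaluated by leave-one-out
cross-validation (LOOCV) → evaluation and baselines.

Decisions where the procedure was genuinely open:

* **Wilcoxon variant.** Exact two-sided p-values when both groups have at
  most 10 cases and no ties; otherwise the normal approximation with
  continuity and tie correction. Constant features get p = 1.
* **Screened-feature ordering.** `wilcoxon_screen()` returns features
  ranked by ascending p-value, and that ranking is the SFS candidate
  ordering. SFS accuracy ties are broken towards the earlier candidate, so
  ties resolve towards the more significant feature — deterministic and
  scientifically sensible. With greedy wrapper selection on small cohorts
  this matters: once LOOCV accuracy saturates, every addition ties, and
  significance ordering is what keeps the selection meaningful.
* **SVM configuration.** Linear kernel, cost 1, per-fold feature
  standardisation (centring/scaling estimated on the 74-case training fold
  only, never on the held-out case). Kernel and cost are config knobs.
* **Normalization scope.** Quantile normalization is applied to the full
  table *before* screening and selection, as the workflow orders the
  steps. This leaks marginal distribution information across LOOCV folds;
  the package documents the caveat, and the per-fold standardisation
  inside the SVM remains strictly leakage-free (verified by a perturbation
  probe in the tests).
* **Cross-validation unit.** The nodule, not the patient. With several
  nodules per patient this can leak patient-level information; real
  multi-nodule cohorts should treat the patient as the unit.
* **Positive class.** Malignant, so sensitivity is the true-positive rate
  among malignant nodules.

The two baselines contextualise the signature: LOOCV accuracy using *all*
screened features, and the mean LOOCV accuracy of random size-4 subsets of
the screened pool (1000 draws by default; seeded and reproducible).

## What the synthetic cohort emulates

`generate_phantom()` renders a spherical nodule of configurable diameter
(the clinical range spans roughly 10–90 mm; defaults use 20 mm at 1 mm
isotropic spacing) over air-like background at −800 HU. In-mask intensity
is a base level (40 HU, soft tissue) plus a correlated Gaussian texture
field: white noise convolved with a Gaussian of the correlation length
(2 mm default), kernel normalised to unit L2 norm so the field keeps the
requested SD (10 HU default). The malignant-like class adds a coarse
heterogeneity component — 3–6 signed Gaussian blobs of scale diameter/6
placed inside the nodule — which is exactly the kind of regional
spot/edge micro-structure the Laws bank detects; benign-like phantoms set
its amplitude to 0. Per-case seeds are `master_seed + case index`, making
cohorts byte-reproducible.

What the phantoms do *not* emulate: lung anatomy (vessels, pleural
attachment), CT physics (beam hardening, reconstruction kernels, dose
noise textures), irregular or spiculated margins, and inter-patient
variability in acquisition. A passing pipeline on phantoms therefore
demonstrates the machinery — inventory completeness, oracle-verified
matrices, selection behaviour, leakage-freedom — not clinical performance
on patient CT.

`simulate_feature_table()` complements the image phantoms at the table
level: it emulates a *screened* feature pool (76 columns by default,
matching the size of a typical screened set) in which exactly 4 planted
columns carry class signal, at 3 SD mean separation by default — signal
well above noise, the regime in which a 4-feature signature saturates and
selection is stressed mainly on its tie handling. Columns are shuffled so
planted features gain no positional advantage. The planted columns carry
the four Laws signature names so recovery can be checked by name.

## Problem sizes and runtime choices

The test-suite and the acceptance script run at deliberately small sizes:
micro-fixtures (≤4³) for the entry-by-entry matrix oracles, 5³–7³ random
patches for the convolution oracles, 10–14 mm phantoms at 1–1.5 mm spacing
for end-to-end extraction, and 20/20-case planted tables over 20 seeds for
the selection-recovery study (with the full 200-draw random baseline
evaluated on three of those cohorts). These sizes were chosen so the whole
suite completes in minutes while keeping every statistical check at the
cohort size the design targets (n = 40).

## Known limitations

* Non-nested selection: the SFS inner accuracy is plain LOOCV on the
  full table, as classically described; a nested scheme would give less
  optimistic signature accuracies.
* No isotropic resampling by default (single-resolution cohorts assumed);
  anisotropic voxels are handled in physical units by the LoG and shape
  code, but matrix features count neighbours in voxel space.
* No intensity windowing/clipping before extraction.
* The run-length "low/high gray-level emphasis" pair uses the standard
  reciprocal-square weights; reversing the gray-level order row-reverses
  the matrix exactly, but maps LGRE to the reflected-weight analogue of
  HGRE rather than to HGRE itself — an algebraic property of the weights
  worth knowing when comparing implementations.
* Wrapper selection on small cohorts overfits: with 72 null candidates at
  n = 40, the best spurious LOOCV gain regularly beats a genuine
  moderate-effect feature. The recovery guarantees quoted in the tests
  hold in the strong-signal regime the generator defaults to, not for
  weak effects.
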