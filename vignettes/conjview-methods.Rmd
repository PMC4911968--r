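---
title: "Methods: planar kidney activity quantification on synthetic SPECT/CT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar kidney activity quantification on synthetic SPECT/CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In ¹⁷⁷Lu radionuclide therapy the kidney is the critical organ, and the most
common dosimetry practice estimates its activity concentration from planar
gamma-camera images. Any planar method must subtract the counts contributed
by tissue over- and underlying the kidney, using a background ROI placed
somewhere near the organ. Because the hottest structures (liver, spleen,
tumours) lie ventrally and cranially to the kidneys, the choice of
background position can change the estimate severalfold. `conjview`
reconstructs this evaluation problem end to end on synthetic phantoms with
known ground truth, so that the behaviour of the conjugate-view (ConjV) and
posterior-view (PostV) estimators under eleven background placements can be
measured rather than argued.

## Model and conventions

All volumes live on a fixed axis convention: axis 1 = left–right (+x =
patient left), axis 2 = anterior–posterior (anterior at index 1), axis 3 =
caudal–cranial (+z = cranial). Planar projections are along axis 2. Masks
use voxel-centre inclusion, which is deterministic and
orientation-independent.

**Attenuation.** CT Hounsfield volumes convert linearly to 208 keV linear
attenuation coefficients, μ = μ_w + HU·μ_w/1000, clamped below at 0. The
effective water coefficient μ_w defaults to 0.136 cm⁻¹ (narrow-beam water at
208 keV) and is a configuration parameter, never a constant baked into
formulas: effective values depend on the camera's energy window and scatter
conditions, so studies must be able to override it.

**Projection.** The attenuated planar image sums each AP column with
exponential attenuation; the emitting voxel contributes half its own μ·Δy to
the path (half-voxel self-attenuation). This convention makes the discrete
sum converge to the continuous slab integral: for a uniform slab the
discrete/continuous ratio is (μΔy/2)/sinh(μΔy/2) ≈ 1 − (μΔy)²/24, about
4·10⁻⁵ at SPECT spacing. The test suite checks the projector against an
independent per-voxel ray-walk oracle to 10⁻¹⁰ relative.

**Estimators.** With A_net and P_net the background-subtracted anterior and
posterior kidney-ROI counts,

* ConjV: AC = μ t_k √(A_net P_net) / [e^(−μ t_p/2)(e^(μ t_k/2) − e^(−μ t_k/2)) v_k]
* PostV: AC = (P_net / v_k) e^(μ d_k) t_k μ / (1 − e^(−μ t_k))

where t_k, t_p are kidney and patient AP thicknesses and d_k the distance
from the posterior body surface to the posterior kidney surface, all
measured on the transverse slice through the kidney centroid along the AP
line through its in-slice centroid; v_k is the kidney volume from the full
3D mask. The μ used here is the scalar μ_w, matching the symbols of the
planar formulas; the voxel μ map is used only for projection. For
μ·t_k < 10⁻⁸ both estimators switch to their exact μ→0 limits
(√(A_net P_net) e^(μ t_p/2)/v_k and P_net e^(μ d_k)/v_k) — a closed-form
guard rather than a series expansion, continuous across the switch to
< 10⁻⁶ relative.

**Regions.** The body mask thresholds the count volume at 5 counts, keeps
the largest 6-connected component and fills holes along AP columns (so that
backprojected columns always span the full body thickness). The kidney VOI
is, in phantom mode, the ground-truth organ mask; a fraction-of-maximum
region grower (threshold = frac × max within a 5 cm probe sphere around a
seed, default frac = 0.5, minimum segment 20 ml) stands in for the
unspecified clinical segmentation when masks are not supplied. The kidney
silhouette, backprojected and clipped to the body, gives the column VOI; the
true background is TB = column − kidney. Background ROIs form a band at
Euclidean distance (2, 6] pixels from the kidney silhouette (gap 2, width
4), split into ten 36° sectors about the real-valued ROI centroid, plus the
surrounding ROI B11 = whole band; the sectors partition B11 exactly by
half-open binning [(k−1)·36°, k·36°).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| μ_w | 0.136 | cm⁻¹ | narrow-beam water at 208 keV; camera-dependent, hence a parameter |
| body threshold | 5 | counts | the level-set value used for body/air separation |
| gap, width | 2, 4 | pixels | stated band geometry around the kidney silhouette |
| n_sectors | 10 | — | 36° sectors B1…B10 |
| frac | 0.5 | — | fraction-of-max region growing stand-in |
| grid, spacing | 128×128×64, 2.21/2.21/4.42 | mm | SPECT matrix and voxel size |
| PSF FWHM | 12 | mm | typical medium-energy-collimator ¹⁷⁷Lu SPECT resolution |
| background | 450 | counts/ml | ≈ 9.7 counts per voxel, enough for the 5-count threshold to work on Poisson data |
| kidney uptake | 10× background | — | clearly elevated renal uptake at 24 h post injection |
| liver uptake | 5× kidney | — | the stated hot cranio-ventral surrogate |
| calibration | 1 | — | relative concentrations; a scalar converts to kBq/ml if wanted |

## The synthetic cohort: what it emulates and what it does not

Each subject is an ellipsoidal torso section (uniform soft-tissue
background, HU ≈ 40) with two ~150 ml dorsal kidneys, a large liver
surrogate placed ventrally and extending cranially over the kidneys, a
smaller spleen surrogate on the left, and one hot tumour in the liver
region. Sizes, positions and uptakes are jittered per subject from a
deterministic seed; blur (FWHM 12 mm) is applied to the activity volume
before Poisson noise, emulating reconstruction resolution and counting
statistics in that fixed order. The liver is placed so that it overlies the
kidneys ventrally rather than purely cranially — the overlap pattern
reported in patients, where ventral overlap inflates the anterior view while
the posterior view stays comparatively clean.

The generator does **not** emulate scatter, collimator depth-dependent
resolution, OSEM reconstruction artefacts, anthropomorphic anatomy, organ
motion, or non-uniform organ uptake. A green cohort test therefore
establishes that the pipeline reproduces the *direction* of the clinical
findings (cranial overestimation and caudal underestimation of the
background, PostV+B11 more accurate than ConjV, PNC ≤ CNC) under the stated
world — not that it reproduces any patient-derived table value, which would
require real paired SPECT/CT scans.

## Numerical choices

* **Blur** uses FFT circular convolution so total counts are conserved to
  machine precision; phantoms keep activity away from grid edges, making
  wrap-around leakage negligible. A truncated spatial kernel with
  zero-padding would lose mass near edges instead.
* **Connected components** are labelled by run-length encoding along x plus
  a union-find over run overlaps; a voxel-wise BFS oracle verifies it in the
  tests. Seed-based region growing uses the BFS directly (small regions).
* **Geometry discretisation**: t_k, t_p and d_k are voxel-count extents
  times the AP voxel size. Because the same voxelised masks drive the
  projector, the slab identity holds almost exactly (relative error ~4·10⁻⁵
  at SPECT spacing, ~2·10⁻⁶ at 4× refinement) even when the slab surfaces do
  not align with voxel boundaries.
* **Negative nets are refusals, not NaNs**: the estimators raise an error
  carrying the negative-net signal, and the report tallies them as CNC/PNC
  percentages; ROIs enter the method comparison only if their negative
  fraction is ≤ 10%.
* **Ties and rounding**: the sector centroid is real-valued (never rounded);
  mask membership uses ≤ on the ellipsoid quadratic form; the angle binning
  is half-open so 36° belongs to B2.

## Open design decisions

* The angle origin (0° = cranial, increasing toward patient left in the
  posterior-view plane) is a declared convention; only the *labelling* of
  sectors depends on it, not any statistic.
* d_k reaches the kidney's **posterior surface**, not its centre, because
  that choice makes the PostV formula exact for a homogeneous slab.
* Background scaling uses the voxel-count ratio
  (column − kidney)/backgroundcolumn, a declared reconstruction of "scaled
  to resemble the over- and underlying tissue volume".
* The cohort CVs use the sample (n−1) standard deviation; subjects with
  negative nets are excluded pairwise from the t-test.
* Organs listed later overwrite earlier ones; extra organs are clipped to
  the body outline so every organ mask is a subset of the body mask.

## Known limitations

* No scatter or septal penetration; μ_w is both the projection medium (via
  HU = 0 tissue) and the correction coefficient, which is kinder to the
  estimators than reality.
* The uniform-background control shows a small (~4%) residual ConjV bias
  from the depth-distribution mismatch between band columns and the
  kidney's over/underlying tissue — inherent to the background-subtraction
  design, and worth remembering when reading the cohort numbers.
* No multiple-testing correction across the 11 ROIs (per-ROI significance
  flags only).
* The fraction-of-max segmenter is a stand-in; with very low contrast or a
  seed outside the kidney it refuses rather than guessing.
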