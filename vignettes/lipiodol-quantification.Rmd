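---
title: "Quantifying Lipiodol deposition on post-chemoembolization CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Lipiodol deposition on post-chemoembolization CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipioquant)
```

## The problem

Conventional transarterial chemoembolization (cTACE) delivers a
chemotherapy–Lipiodol emulsion into the hepatic-artery branches feeding a
liver tumor. Lipiodol is radiopaque, so a non-contrast CT acquired about 24
hours after the procedure shows where drug was actually delivered: its CT
attenuation, in calibrated Hounsfield units (HU), is a surrogate for local
drug concentration. `lipioquant` implements a fully automated, threshold-based
volumetric analysis of such scans: it stratifies Lipiodol by density,
classifies each lesion's spatial deposition pattern, and relates deposition to
tumor devascularization measured on contrast MRI before and after treatment.

Inputs are NIfTI volumes and 0/1 masks: the 24 h CT, arterial-phase baseline
and follow-up MRI, binary tumor segmentations for each time point (produced by
segmentation software — segmentation itself is out of scope), a ~1 cm³
background-parenchyma VOI on each MRI, and one or more "no-Lipiodol
parenchyma" sample regions on CT.

## Density thresholds

Lipiodol density is stratified by three HU cut-offs `t_min < t_low_mid <
t_mid_high`, with strict-above boundary semantics everywhere: a voxel
*contains Lipiodol* iff HU > `t_min`; low density is `(t_min, t_low_mid]`, mid
`(t_low_mid, t_mid_high]`, high above `t_mid_high`.

* **`t_min`** is the 99th percentile of voxel intensities in Lipiodol-free
  parenchyma samples. All percentiles in the package use linear interpolation
  between order statistics (rank `1 + p(n-1)`, R's `quantile` type 7); the
  convention is stated once here and used identically everywhere.
* **Per-tumor bilevel thresholds.** Each tumor's Lipiodol-positive voxels
  (HU > `t_min`) are split into lower- and higher-density deposition by two
  bilevel histogram thresholders — maximum between-class variance (Otsu) and
  minimum cross-entropy (Li) — both as exhaustive searches over integer-HU
  candidate cuts on `[min, max)` of the sample. HU is an integer-calibrated
  scale, so the integer grid keeps the search and any independent oracle on
  the same footing. Ties are broken toward the smallest optimal candidate for
  determinism; note that on histograms with an empty gap between modes every
  cut inside the gap is exactly equivalent, so the reported threshold sits at
  the low edge of the optimal plateau. The cross-entropy criterion needs
  positive intensities (it takes logarithms of class means); in the pipeline
  it only ever sees values above `t_min`, and the operator shifts non-positive
  samples up front and shifts the result back otherwise.
* **Scope.** Whether the bilevel split should see the full tumor histogram or
  only Lipiodol-positive voxels is genuinely open; the package defaults to
  Lipiodol-positive voxels, because the split is meant to separate regions of
  lower and higher *deposition* and including non-Lipiodol tissue drags the
  threshold toward parenchyma. `per_tumor_threshold(scope = "full_tumor")`
  selects the other reading. Tumors with fewer than 50 Lipiodol-positive
  voxels are flagged and skipped, not errored.
* **Cohort pooling.** The 33rd percentile of per-tumor thresholds separates
  low from mid density, the 67th mid from high. Two orderings of the
  percentile and cross-technique averaging steps are plausible;
  `percentile_then_average` (percentile per technique, then average) is the
  default because the published per-technique percentiles (159/239 HU
  cross-entropy, 151/243 HU variance) average exactly to the published
  155/241 HU cut-offs. `average_then_percentile` implements the other
  reading; the two coincide whenever the techniques agree per tumor.

```{r thresholds}
cohort_thresholds(data.frame(t_ce = c(159, 159, 239, 239),
                             t_var = c(151, 151, 243, 243)),
                  mode = "percentile_then_average")[1:2]
```

`default_thresholds()` (87/155/241 HU) applies the published cut-offs
directly, skipping cohort derivation.

## Deposition patterns

Four features, all cut-offs collected in `pattern_config()` with the
published values as defaults:

* **Homogeneous**: ≥ 85% of the tumor volume is mid- or high-density.
* **Sparse**: ≤ 20% mid *and* ≤ 10% high density. "Medium" is read literally
  as the mid class alone (not mid-or-high); `sparse_mid_includes_high = TRUE`
  switches the other reading. All three comparisons are inclusive.
* **Rim**: the tumor is eroded by 15% of its equivalent-sphere radius
  (`r_eq = (3V/4π)^{1/3}`), the remainder is the rim shell. The base intensity
  is `max(t_min, mean core HU)`; the rim score is the mean over rim voxels of
  `max(0, HU − base)`, and the lesion is rim-depositing iff the score
  reaches 17 HU. The cut-off is applied to the score (already an excess over
  base) rather than to `mean rim HU − base`; the two differ only through the
  clamping at zero, and the score reading follows directly from the score's
  definition. Erosion and dilation are implemented with a Euclidean distance
  transform in physical millimetres, so they behave correctly on anisotropic
  grids; a consequence is that erosion distances below the voxel size remove
  nothing, leaving small lesions with an empty rim shell — such lesions are
  flagged "rim undefined" rather than scored.
* **Peripheral**: the percentage of the 3.5 mm band outside the tumor surface
  whose voxels exceed `t_min`. All periphery voxels are counted (no attempt
  to exclude vessels); a band clipped by the volume border is flagged.

`classify_pattern()` composes these into the taxonomy — well-delineated
lesions are homogeneous or rim/non-rim × sparse/non-sparse, infiltrative
lesions sparse/non-sparse — with the growth type taken from the manual lesion
record, never inferred. Rim is only evaluated for well-delineated lesions.

## qEASL response

On each MRI, the enhancement threshold is the parenchymal VOI mean plus two
standard deviations (population SD — at ~10³ voxels the sample/population
difference is negligible, but it is pinned for determinism). A tumor voxel is
viable iff its signal is ≥ that threshold (inclusive). Enhancement is raw
arterial-phase signal by default; a pre-contrast volume can be supplied for
subtraction mode. The enhancing tumor volume (ETV) is the physical volume of
the viable compartment; lesions respond iff ETV falls by at least 65%
(inclusive), and lesions with zero baseline ETV are excluded rather than
divided by. Regional analyses (e.g. conversion rates stratified by Lipiodol
density class) always run in CT space on registered masks, never in native
MRI space, and skip regions under 50 voxels.

## Registration

Both MRI tumor masks are registered *to* the 24 h CT tumor mask. The
deformation is driven by the binary masks, not the raw images — image-driven
registration would preferentially align bright voxels (enhancing tumor,
dense Lipiodol) and bias exactly the intensity analyses this package runs
afterwards. The masks are rigidly pre-aligned by centroid translation (without
it, distant masks stall the iteration), then a demons iteration on
Gaussian-smoothed mask images refines the field: Thirion forces with a
per-iteration step cap, fluid-like smoothing of each increment and
diffusion-like smoothing of the accumulated field. The contract is enforced,
not assumed: Dice overlap must not decrease (else an error carrying both Dice
values), and the Jacobian determinant of `x → x + u(x)` must be positive at
every voxel. Hyperparameters (iterations, three smoothing sigmas, step cap)
are not dictated by the source analysis; `demons_config()` documents the
defaults and everything is overridable. Intensity images are resampled with
trilinear interpolation; masks and label maps are categorical and must use
nearest-neighbour — a linear request on a mask is an error, and masks never
get resampled implicitly anywhere else in the package.

## The phantom generator

Because no imaging data accompany the source cohort, every analysis operation
is validated on seeded synthetic phantoms with known ground truth
(`phantom_config()` / `generate_phantom()` / `generate_cohort()`). Defaults:
64³ grids at 1 mm isotropic spacing, liver background N(55, 8) HU, deposits at
N(120, 15) / N(195, 20) / N(300, 30) HU for low/mid/high — chosen to straddle
the 87/155/241 HU cut-offs — and 30 mm lesions (well above the 1 cm inclusion
rule). `noise_scale = 0` gives noise-free volumes whose voxels sit exactly at
the class means, closing the generator/classifier loop exactly. Deposits are
carved from a smoothed noise field as deterministic voxel counts, so fill
fractions are exact and spatially coherent; the seven archetypes place them
per pattern (dense rim over empty core, core-weighted fill, peripheral halo in
the 3.5 mm band, and so on). MRI phantoms place an enhancing compartment of a
configured fraction at high signal, and the follow-up flips baseline-viable
voxels to non-enhancing with probabilities (default 0.2/0.4/0.6/0.8 for
none/low/mid/high) that increase with the local Lipiodol density class —
the generative analogue of the observation that deposition predicts
devascularization.

What the phantoms do *not* emulate: anatomy (vessels, bile ducts, adjacent
organs), partial-volume effects at deposit boundaries, beam-hardening/streak
artifacts around dense Lipiodol, segmentation error, or inter-scanner HU
drift. Passing tests therefore demonstrate correctness of the measurement
pipeline under its stated model, not clinical performance on patient images.

A single master seed streams per-case seeds in `generate_cohort()`, making
whole cohorts bit-reproducible; the generator saves and restores the caller's
RNG state.

## Statistics

`compare_groups()` and `peripheral_regression()` are a deliberately thin
layer over `wilcox.test`, `kruskal.test`, `fisher.test`, `lm` and `cor.test`:
they add input validation, the degenerate signed-rank convention (statistic 0,
p = 1 when all paired differences vanish — base R refuses that case), and a
tidy result row. All tests are two-sided; no multiplicity correction is
applied, matching the source analysis.

## Numerical choices and degenerate inputs

* Distance transforms: exact Euclidean (separable parabola envelopes) with
  per-axis spacing; distances are voxel-centre to voxel-centre.
* Bilevel thresholders error on constant input ("degenerate histogram");
  candidate grids are integer HU.
* `physical_volume` of an empty mask is 0 with a warning; empty tumor masks
  are rejected at construction.
* Geometry matching is exact to 1e-6 mm; nothing resamples implicitly.
* Cohorts with fewer than 3 threshold-eligible tumors fall back to the mean
  per-tumor threshold with a warning; a single excluded lesion never aborts a
  cohort run (it is recorded in the manifest with its stage and reason).

## Problem sizes

The shipped tests and the acceptance script run on 64³ phantom grids; the
pattern-recovery study uses 200 phantoms across the seven archetypes at 5 HU
class noise plus a noise-free set, the registration checks use a 4 mm
translated sphere and an equal-volume 1.3-axis-ratio ellipsoid, the
density-stratified response phantom holds ≥ 2000 baseline-viable voxels per
density stratum, and the regression recovery uses a 200-lesion synthetic
cohort. These sizes give sub-voxel-level agreement checks while keeping a
full run in the low minutes on one core.

## Known limitations

* Axis-aligned geometry only: NIfTI orientation matrices are reduced to axis
  directions; oblique acquisitions should be reoriented upstream.
* The demons implementation is mask-driven by design and has no multiresolution
  pyramid; it is adequate for the small inter-timepoint deformations of
  registered tumor masks, not for whole-organ registration.
* Cone-beam CT is unsupported (uncalibrated HU), as is DICOM series reading —
  convert to NIfTI first.
* Well-delineated vs infiltrative growth is a manual input by design.
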