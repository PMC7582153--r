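# lipioquant

Automated, threshold-based volumetric quantification of Lipiodol deposition
on 24-hour post-cTACE CT, for interventional-radiology image analysis.

In conventional transarterial chemoembolization (cTACE) of liver cancer, a
chemotherapy–Lipiodol emulsion is delivered into the tumor's hepatic-artery
feeders. Lipiodol is radiopaque, so the non-contrast CT acquired ~24 h after
the procedure maps drug delivery in calibrated Hounsfield units (HU).
`lipioquant` turns that scan — plus baseline and follow-up arterial-phase MRI
and their tumor segmentation masks — into quantitative imaging biomarkers:

* **Density stratification.** Three HU cut-offs `t_min < t_low_mid <
  t_mid_high` label every tumor voxel none/low/mid/high. `t_min` is the 99th
  percentile of Lipiodol-free parenchyma samples; per-tumor thresholds come
  from two bilevel histogram criteria — maximum between-class variance
  (Otsu) and minimum cross-entropy (Li), both exhaustive over integer-HU
  cuts — and the cohort cut-offs are the 33rd/67th percentiles of those
  thresholds across tumors, averaged over the two techniques. The published
  values 87/155/241 HU ship as `default_thresholds()`.
* **Deposition patterns.** Homogeneous (≥ 85% of the tumor mid/high
  density), sparse (≤ 20% mid and ≤ 10% high), rim (mean excess over the
  core's base intensity in the outer 15%-of-equivalent-radius shell
  ≥ 17 HU), and peripheral coverage (% of the 3.5 mm band outside the tumor
  above `t_min`) — all morphology in physical millimetres via exact
  Euclidean distance transforms.
* **qEASL response.** Viable tumor = voxels ≥ VOI mean + 2 SD on
  arterial-phase MRI; enhancing tumor volume (ETV), percent ETV change, the
  ≥ 65%-reduction responder rule, and density-stratified devascularization
  rates computed in CT space on registered masks.
* **Mask-driven registration.** Diffeomorphic-demons deformation derived
  from the binary tumor masks (MRI → CT), with centroid pre-alignment,
  enforced Dice monotonicity and everywhere-positive Jacobian, and
  label-safe (nearest-neighbour) resampling of compartment masks.
* **Synthetic phantoms.** A seeded generator produces CT + MRI cases with
  known density, pattern and response ground truth across seven deposition
  archetypes, standing in for clinical images in every test.

## Worked example

Generate a small synthetic cohort, derive cohort thresholds from it, and run
the full two-pass analysis:

```r
library(lipioquant)

coh <- generate_cohort(6, master_seed = 42)
res <- run_cohort(coh$cases)
res
#> <cohort_result> 6 lesions (6 analyzed, 0 excluded); thresholds 73.3152/120.3/210.075 HU
res$features[, c("lesion_id", "category", "frac_any", "pct_change", "responder")]
#>   lesion_id            category  frac_any pct_change     responder
#> 1  case-001         homogeneous 0.9507142  -65.15576     responder
#> 2  case-002 infiltrative sparse 0.1591321  -22.77054 non_responder
#> 3  case-003          rim sparse 0.1840422  -27.19219 non_responder
#> 4  case-004      rim non-sparse 0.5254607  -43.58255 non_responder
#> 5  case-005      non-rim sparse 0.1601046  -22.23569 non_responder
#> 6  case-006  non-rim non-sparse 0.5265882  -40.35296 non_responder
```

The derived cut-offs (73/120/210 HU here) reflect the phantom cohort's own
deposit HU mixture — on clinical data calibrated like the source cohort they
would sit near 87/155/241 HU, and those published values can be applied
directly via `pipeline_config(thresholds = default_thresholds())`. Each row
joins the lesion's Lipiodol coverage (`frac_any`: fraction of tumor voxels
containing Lipiodol of any density), its deposition-pattern category, and
its qEASL response (percent ETV change; responder = reduction ≥ 65%). The
homogeneously filled lesion responds; the sparse ones do not — the
association the density-conditional response model of the generator encodes.

Per-lesion pieces are available individually:

```r
case <- coh$cases[[3]]
map <- classify_density(case$ct, case$tumor_mask, res$thresholds)
map
#> <density_label_map> 20479 tumor voxels: none 16710, low 182, mid 2803, high 784
classify_pattern(map, case$ct, case$tumor_mask, res$thresholds$t_min, case$lesion)
#> <pattern_report> case-003 (well_delineated): rim sparse | mid+high 17.5%, rim score 48.8 HU, peripheral 1.1%
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/lipioquant` (subcommands `phantom`, `classify`, `thresholds`,
`cohort`).

## Methods

See the methods vignette (`vignettes/lipiodol-quantification.Rmd`) for the
model, parameter meanings and defaults, the phantom generator's scope and
limits, and the numerical conventions (percentile interpolation, boundary
semantics, tie-breaking).
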