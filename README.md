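# spatzone

Zonal analysis of highly multiplexed tissue images (imaging mass
cytometry and kin) for the tumor immune microenvironment, built around two
ideas:

1. **Spatial subsetting.** Regions of interest (ROIs) differ widely in how
   much tumor they contain, so raw per-population cell counts mostly
   measure tumor-covered area. `spatzone` converts a binary tumor mask into
   an exact signed Euclidean distance map, assigns every cell to the
   **stroma** (> 20 µm outside the border), **tumor front** (within 20 µm
   of the border, both sides) or **tumor core** (> 20 µm inside), and
   normalizes features per zone. Zone areas come from the same distance
   thresholds ($A_e$ = pixels within +20 µm, $A_s$ = pixels deeper than
   −20 µm; stroma $= A_{ROI}-A_e$, front $= A_e-A_s$, core $= A_s$), so
   areas and per-pixel zones can never disagree and always partition the
   ROI exactly.

2. **Stability-selection late fusion.** Four zone-resolved feature classes
   — zonal densities (cells/mm²), mean arcsinh-transformed functional
   marker expression, spatial metavariables (cell size, eccentricity,
   border distance at the front), and neighborhood coefficients (type
   proportions among each cell's ≤ 5 nearest neighbors within 20 µm) — are
   each screened by bootstrapped LASSO (500 subsamples of 50% of the
   training data; features selected in > 50% of iterations are kept, with
   the per-subsample support capped at $\lceil\sqrt{p}/2\rceil$ to keep
   the selection sparse). The selected features from all classes feed one
   logistic regression classifying histological grade, evaluated by
   patient-grouped 5-fold Monte Carlo cross-validation with pooled
   out-of-fold AUROC.

A seeded synthetic cohort generator reproduces the statistical structure
this pipeline assumes (1000 × 500 µm ROIs at 1 µm/pixel, 15 populations
with zone-dependent densities, 14 functional markers, 3 ROIs per patient
with intrapatient correlation, planted grade effects), so the whole chain
is testable end to end without any imaging data. Variability analytics
(intrapatient / interpatient / inter-cohort CVs and correlations) quantify
what the zonation buys in reproducibility.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated 24-patient cohort. Generating the cohort and quantifying the
tumor-area bias (`analysis/01`, `analysis/02`) prints:

```
Generating 24-patient synthetic cohort (seed 1001 )...
  81305 cells across 72 ROIs (24 patients)
  QC removed 0 small objects and 6595 DNA outliers (8.1%)
  gating recovered the generating population for 99.98% of cells
...
Median |rho| across populations: 0.64 (raw counts) -> 0.06 (zonal densities)
```

Raw counts correlate strongly with the tumor-covered fraction (|ρ| ≈ 0.64
across populations — the bias), while zonal densities do not (|ρ| ≈ 0.06) —
the decorrelation that motivates spatial subsetting. Feature assembly
(`analysis/03`) yields 1281 features over 72 ROIs (45 density + 574
function + 97 metavariable + 565 neighborhood after the median-zero
exclusion rule drops 4 of 45 population-zone combinations), and the
classifier (`analysis/05`) recovers exactly the planted grade biology:

```
final model: 13 selected features
   density:stroma:cd4_memory
   density:front:tumor_prolif
   density:core:tumor_nonprolif
   function:front:granulocyte:pMAPKAPK2
   metavariable:stroma:cd4_memory:size
   metavariable:front:fibroblast:border_dist
   neighborhood:front:tumor_prolif:tumor_prolif
   ...
13 of 13 model features have p < 0.05 (uncorrected)
```

The six planted effects (three density shifts, granulocyte pMAPKAPK2
signaling at the front, stromal CD4 memory T-cell size, fibroblast border
distance) are all selected, alongside neighborhood coefficients that are
their correlated spatial proxies; on this strongly planted cohort the
pooled cross-validated AUROC saturates at 1.0.

Programmatic use mirrors the scripts:

```r
library(spatzone)
co    <- generate_cohort(cohort_config(seed = 1))
cells <- gate_cell_types(qc_filter(co$cells))
cells$population <- cells$type_label
fm    <- assemble_feature_matrix(cells, co$zones, co$meta)
res   <- monte_carlo_cv(fm, stability_config(seed = 2))
res$auc
```

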