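---
title: "Spatial subsetting and integrative modeling of multiplexed tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial subsetting and integrative modeling of multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatzone)
```

## The problem

Highly multiplexed tissue imaging (imaging mass cytometry, CODEX, MIBI)
measures dozens of protein markers per cell at micrometre resolution, over
small regions of interest (ROIs) sampled from a tumor section. Two
structural properties of such data confound naive per-ROI summaries:

* the **tumor-covered fraction** of an ROI varies widely between images, so
  raw per-population cell counts largely measure how much tumor happened to
  be in the frame rather than any biology of the tumor immune
  microenvironment (TIME);
* ROIs from the same patient are **correlated**, so patient-level claims
  need variability analytics that distinguish intrapatient, interpatient
  and inter-cohort heterogeneity.

`spatzone` implements the spatial-subsetting remedy and the downstream
integrative classifier. Every analysis step lives in the package; the
numbered scripts under `analysis/` are thin narrative drivers.

## Zonation relative to the tumor border

A binary tumor mask is converted to a **signed Euclidean distance map**: the
border set consists of tumor pixels 4-adjacent to background, distances are
exact (Felzenszwalb–Huttenlocher transform, center-to-center on the pixel
lattice, scaled by `pixel_size`), negative inside the tumor and positive
outside. Each cell receives the signed distance of minimal absolute value
over its boundary pixels, and is assigned to one of three zones:

* **tumor core** — deeper than 20 µm inside the border,
* **tumor front** — within 20 µm of the border on either side (closed
  interval, so exact ties at ±20 µm fall into the front),
* **stroma** — farther than 20 µm outside.

Zone areas use the same distance thresholds, not structuring-element
morphology: the expanded tumor area $A_e$ collects pixels with distance
$\le +20$ µm, the shrunken area $A_s$ pixels with distance $< -20$ µm, and
stroma $= A_{ROI} - A_e$, front $= A_e - A_s$, core $= A_s$. Because pixel
zones and areas derive from one distance map, the three zone areas always
partition the ROI exactly (in pixel counts), and per-pixel zones can never
disagree with the areas.

Degenerate masks are handled with sentinels: an empty mask has no border,
every pixel gets $+\infty$ and every cell is stroma; a full mask (the image
edge is *not* treated as background) gets $-\infty$ and every cell is core.
For a full mask the distance-threshold "shrink" removes nothing, so the core
is the whole ROI — a documented convention, exercised by the tests.
Multi-component masks need no bookkeeping: the distance map is to the
nearest border of any component.

**Zonal density** of a population is its cell count in a zone divided by
the zone area (cells/mm²). A zone with zero area yields a *missing* density,
never a zero: absence of tissue is not absence of cells.

## Feature classes

Per ROI the package builds four feature classes, all zone-resolved, named
`class:zone:population[:marker|:metric|:partner]`:

1. **density** — zonal densities over the full 15 populations × 3 zones
   grid (45 columns, always);
2. **function** — mean arcsinh-transformed intensity (cofactor 1) of the 14
   functional markers per population and zone;
3. **metavariable** — mean cell size and mean eccentricity per population
   and zone, plus the mean signed border distance per population for the
   front zone only (elsewhere the distance mostly reflects the ROI's
   tumor-area geometry);
4. **neighborhood** — per center cell the proportions of its up-to-5
   nearest neighbors (within 20 µm) per population, averaged over the
   center cells of each population within each zone (the zone of the
   *center* cell).

The default neighbor distance is border-to-border: the minimum distance
between boundary pixel sets when label masks are available, and the
equivalent-circle surrogate (centroid distance minus both radii, floored at
0) for point-mode synthetic cells; a centroid mode exists for speed. Cells
with no neighbor within the cutoff contribute nothing to the means, and a
cell's coefficient vector sums to one whenever it has at least one
classified neighbor.

An **exclusion rule** keeps the three non-density classes honest: a
(population, zone) combination whose *median* zonal density across ROIs is
zero is excluded from the function, metavariable and neighborhood classes
of that zone — otherwise those features would be driven by a handful of
ROIs that happen to contain the population at all. The density class is
never filtered. Neighborhood features require both the center and the
partner population to be retained in the zone. ROIs lacking a retained
combination produce missing values; imputation (training-split medians)
happens only inside modeling folds, never at assembly time, so absence is
never silently conflated with low signal.

## Phenotyping and QC

Mean marker intensities are arcsinh-transformed with cofactor 1. The QC
filter removes segmented objects smaller than 10 pixels and cells whose
DNA intercalator signals lie outside mean ± 2 SD, with the statistics
computed per cohort on the pre-filter table; a zero-spread cohort disables
the DNA rule with a warning, and refiltering with frozen statistics is
idempotent.

Cell types are assigned by **deterministic threshold gating** on the
canonical lineage markers (panCK/Ki67 for tumor cells; CD45/CD3/CD4 with
FoxP3/CD45RA for the CD4 compartment; CD8; CD20; CD68/CD163/CD206 for
macrophage polarization; CD14/CD11b/HLA-DR for monocytic subsets including
MDSCs; CD11c; CD31/aSMA; collagen), evaluated as an ordered rule list with
`unclassified` as the total fallback. Graph-based clustering, which the
field often uses instead, is deliberately out of the package: externally
computed labels can be injected verbatim via `external_labels`, making the
gate a pluggable stage. Cell eccentricity is defined by the second-moment
ellipse, $\sqrt{1 - \lambda_2/\lambda_1}$ with the 1/12 pixel-extent
correction (the common regionprops convention), since the quantity is
otherwise convention-dependent.

## Variability analytics

The coefficient of variation (sample SD / mean; missing when the mean is
zero) is computed **intrapatient** (across the ROIs of one patient) and
**interpatient** (across patients, after a seeded random draw of one ROI
per patient; averaging over several draws is available to reduce
Monte-Carlo noise, one draw is the default). Reproducibility is summarized
two ways, both Spearman: inter-cohort correlation of per-cohort feature
means matched by feature name, and the pooled correlation over all
within-patient ROI pairs. Computing both on raw counts and on zonal
densities quantifies what spatial subsetting buys: on simulated twin
cohorts differing only in ROI sampling, the after-subsetting correlations
exceed the before-subsetting ones.

## The classifier

The grade model is a **late-fusion** design. Within each feature class,
**stability selection** runs 500 bootstrap iterations; each iteration
subsamples 50% of the training samples without replacement
(class-stratified), standardizes the subsample, fits a LASSO, and records
the support. A feature's selection frequency is the fraction of iterations
selecting it, and features above the 0.5 threshold are kept. The fused
model is an unpenalized logistic regression on the union of the selected
features (ridge-stabilized with a warning under separation; an empty
selection degenerates to an intercept-only model scoring the training
prevalence).

The LASSO minimizes the squared-error objective
$\lVert Y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$ on 0/1-encoded
labels — squared error, not the logistic likelihood, matching the selection
procedure's definition; an L1-logistic variant was considered and rejected
as the default because the selection step only consumes the support. The
solver is cyclic coordinate descent with active-set iteration and warm
starts along a log-spaced path; on orthonormal designs it reproduces the
soft-threshold closed form to machine precision, and it is cross-checked
against an independent solver in the tests.

**Per-iteration penalty.** The selection procedure does not uniquely fix
how $\lambda$ is chosen per bootstrap, and the choice matters. Four rules
are implemented:

* `support` (default): walk the path from $\lambda_{max}$ down and stop at
  the largest penalty whose support reaches $q = \lceil\sqrt{p}/2\rceil$
  features — the classical stability-selection device of capping how many
  variables each subsample may admit. Calibration simulations (planted
  effects at $d = 1.2$ among noise, and pure-noise nulls) show this rule
  recovers ≥ 70% of planted features at frequency > 0.5 while admitting
  ≤ 5% of noise features.
* `cv_min`: per-bootstrap inner 5-fold CV over a shared grid. Simulations
  show CV-min is far too liberal here — roughly a third of pure-noise
  features exceed the 0.5 frequency threshold — so it is available but not
  the default.
* `fixed`: a user-supplied penalty.
* `max_path`: score each feature by its maximum selection frequency over
  the whole grid.

**Monte Carlo cross-validation.** Five folds; each draws a random 80/20
split grouped by patient, so the three ROIs of a patient never straddle
train/test (ROI-level splitting is available to mimic an
independence-of-images assumption, but grouping is the default because
sibling ROIs are strongly correlated). All leak-prone statistics —
imputation medians, standardization, selection frequencies — are computed
on the training side only; a corruption canary in the tests verifies that
altering held-out rows changes nothing about the fold's selection or fit.
Held-out scores are pooled over folds for the AUROC. Before pooling, each
fold's scores are centered at the fold's training prevalence: pooled
out-of-fold scores from different models are only rank-comparable after
aligning their operating points, and without centering a fold whose model
is intercept-only would rank its held-out samples by training prevalence —
which anti-correlates with the held-out class mix under grouped splits and
collapses the null AUC toward 0 instead of 0.5. With centering, constant
folds contribute exact ties. The final feature list comes from stability
selection on the entire dataset.

AUROC uses the rank (Mann–Whitney) formulation with tie correction, a
stratified bootstrap percentile CI (2000 replicates, seeded), and a
two-sided Mann–Whitney p-value for score separation. The Mann–Whitney test
itself enumerates all group assignments exactly (ties included) when the
pooled size is ≤ 12 and otherwise uses the tie-corrected normal
approximation with continuity correction. The univariate screen applies it
per feature at ROI level, uncorrected for multiple testing — deliberately,
as a descriptive companion to the multivariable model, and prominently
labelled as such.

## The synthetic cohort generator

All statistical claims above are exercised on seeded synthetic cohorts
(`generate_cohort()`), built to mimic the study design the pipeline
targets: 24 patients per cohort, 3 ROIs per patient, 1000 × 500 µm ROIs at
1 µm/pixel (500,000 pixels), tumor-covered fraction drawn uniformly from
[0.1, 0.8], 15 populations, 14 functional markers, balanced binary grade
labels across patients.

* **Tumor masks** are thresholded smoothed Gaussian random fields; the
  threshold is the order statistic matching the target fraction, so the
  achieved fraction is exact to pixel resolution and the borders have both
  convex and concave stretches (nontrivial band areas).
* **Cells** are placed by an inhomogeneous Poisson process with per-zone
  intensities from the population table, scaled by patient- and ROI-level
  lognormal factors. The total log-scale density SD is 0.3, split so the
  correlation of log-densities between ROIs of one patient equals
  `intrapatient_corr` (default 0.6). The 0.3 calibration keeps realistic
  biological spread while letting tumor-area variation dominate raw tumor
  counts — the premise that motivates spatial subsetting in the first
  place; with much larger density noise the generator would no longer
  exhibit the count-vs-tumor-area bias the method corrects.
* **Markers** are drawn on the arcsinh scale around population-specific
  locations (gate markers: clearly positive vs background, tighter
  cell-level noise; functional markers: a shared baseline plus between-ROI
  wobble), then stored raw via `sinh`, so the intensity distribution is
  right-skewed as in mass cytometry and the arcsinh transform is
  meaningful. Default gating thresholds sit at the midpoint of the marker
  model's positive and negative locations.
* **Grade effects** are planted as standardized mean differences
  (`effect_spec`): density effects rescale counts (thinning or
  duplication-with-jitter), function and metavariable effects shift the
  named per-ROI quantity by `effect_size` SDs of that feature measured
  across all ROIs before shifting. Planting a neighborhood coefficient
  would require rearranging cell positions post hoc and is not supported —
  the constructor accepts the class for completeness but planting raises
  an informative error.
* In the default **points mode**, cells carry parametric geometry (area,
  eccentricity, equivalent radius) and zone membership from the distance
  map at their centroid; `render_masks = TRUE` additionally rasterizes each
  cell as an oriented ellipse with overlap resolution (local re-placement,
  then shrinking), for workflows that need label masks.

The generator emulates the *statistical structure* of an IMC study —
zone-dependent composition, patient correlation, marker skew, planted
effects — not its imaging physics: there is no spillover, no hot pixels, no
segmentation error, no spatial clustering of cells beyond zone membership,
and marker correlations within cells are limited to what the population
profiles induce. Passing tests therefore demonstrate that the *pipeline*
behaves correctly under the assumed data-generating structure, not that
any biological conclusion transfers to real tissue.

For the modeling stage specifically, `simulate_feature_matrix()` plants
effects directly at the feature level (24 patients × 3 ROIs, unit-variance
features split between a patient random effect and ROI noise, a
1.2-SD shift in 10 informative features distributed round-robin over the
four classes) — the cleanest way to measure selection recovery and false
selection without the image-level machinery in between.

## Numerical choices and degenerate inputs

* Distance ties at ±20 µm: front (closed interval), configurable.
* Cells straddling the border: distance 0, hence front.
* CV with mean 0, Spearman with zero variance: missing with a warning,
  never a crafted number.
* Mann–Whitney with all values tied: exact enumeration returns p = 1.
* Subsamples with a single class: redrawn (bounded retries), then an error.
* Standardization of a zero-variance feature maps it to all-zero (it can
  never be selected in that subsample).
* Coordinate-descent tolerances: 1e-10 for single fits (closed-form
  agreement), 1e-7 with capped sweeps inside the bootstrapped path fits,
  where only the support matters.

## Problem sizes used by the test-suite and reproduction script

The test suite and `scripts/acceptance.R` run the full study-shaped designs
where the claim depends on them (72-ROI cohorts for decorrelation and
planted-effect recovery; 500-bootstrap stability selection with 5 Monte
Carlo folds for the modeling claims; 2000-replicate null calibrations) and
deliberately small cohorts elsewhere (oracle comparisons on ≤ 64 × 64
fixtures, 30-cell neighborhoods) — chosen so every check measures what it
claims to measure at the scale the claim is about.

## Known limitations

* The gate is a stand-in for clustering-based phenotyping; real data
  should inject its own labels.
* The equivalent-circle border surrogate underestimates border distances
  for elongated cells (fibroblasts); mask rendering gives exact borders at
  higher cost.
* Interpatient CV from a single ROI draw is noisy by construction
  (`n_draws` mitigates).
* The pooled, prevalence-centered AUROC is one defensible convention for
  Monte Carlo CV; per-fold AUROC averaging is a reasonable alternative the
  package does not implement.
* The univariate screen is uncorrected by design and must not be read as a
  discovery procedure.
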