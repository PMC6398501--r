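---
title: "Methods: quantifying protein aggregation in screens and brains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protein aggregation in screens and brains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscreen)
```

## The two assays

`aggscreen` implements the quantitative machinery of a cell-based RNAi
screen for modifiers of aggregation of a GFP-tagged, disease-mutant VAP
protein (the *Drosophila* orthologue of human VAPB carrying the ALS8
mutation), together with the companion in vivo assay that measures
aggregation density in 3D confocal stacks of the larval ventral nerve cord.

In the cell assay, S2R+ cells expressing the mutant fusion under an
inducible promoter form bright intracellular puncta; the per-well phenotype
is the distribution of per-cell GFP intensity, and a knockdown that shifts
that distribution down (fewer/weaker puncta) is a candidate suppressor,
while a shift up marks an enhancer. At the screen's working point (500 uM
CuSO4, 24 h post-induction) more than 80% of mutant-expressing cells carry
puncta, against fewer than 10% for the wild-type protein, whose signal is
diffuse and reticular (ER-like). In the brain assay, aggregates are counted
as bright 3D objects per cubic micrometre of ventral nerve cord tissue and
compared between genotypes after normalizing to the control group's mean.

Because the original screen images are not publicly deposited, the package
ships a synthetic-data module that generates two-channel fields, whole
384-well plates and 3D stacks with planted ground truth. All quantitative
claims made by the test suite are claims about recovery of that planted
truth.

## The synthetic data generator

A field is rendered from a `field_spec()`:

* **Nuclei** are Gaussian-profile ellipses (axis ratio at most 1.5, random
  orientation, per-cell amplitude drawn uniformly within +/-20% of the
  nominal 150 AFU). Centres are placed by dart throwing with a minimum
  separation of twice the nucleus radius plus 2 px, so nuclei never overlap
  and a placement that cannot fit raises an error suggesting a larger
  field. The default field holds 400 cells of radius 10 px in a 1024 px
  square, matching the screen's ~400 cells per field at a cellular radius
  of ~10 px (5 um at 20x).
* **Positivity** is decided per cell by comparing a uniform draw against
  `positive_fraction`. The draws come from a dedicated random substream, so
  at a fixed seed the positive set grows monotonically with the fraction —
  useful for coupling experiments — and the per-field positive count is
  binomial, reproducing the sampling noise implied by fractions reported
  over thousands of cells.
* **Puncta**: each positive cell receives 1-3 puncta (truncated Poisson,
  mean 1.5) of diameter 3-7 px, rendered as flat-topped disks with a ~1 px
  soft shoulder (a minimal stand-in for diffraction blur), placed without
  mutual contact within 0.6 cell radii of the cell centre (aggregates
  cluster near the nucleus/ER, and keeping them central limits spurious
  merging of neighbouring cells' puncta by the counting macro).
* **Diffuse signal**: every cell carries a dim disk of reticular signal
  (default 20 AFU against a punctum intensity of 200 AFU). This is what
  makes the wild-type-like condition non-trivial for the counting pipeline.
* **Illumination and noise**: both channels are multiplied by a random
  low-order polynomial surface with a configurable peak deviation (default
  15%) and receive additive Gaussian noise (default sd 4 AFU), floored at
  zero.

The dose/time model is linear with clipping:
`fraction = clip01(baseline + slope_conc * conc + slope_time * hours)`.
Defaults (`slope_conc = 0.001` per uM, `slope_time = 0.005` per hour,
`baseline = 0.23`) are chosen so the screen's working point of (500 uM,
24 h) gives a true fraction of 0.85 and the fraction still rises between
24 h and 36 h, while wild-type-like fields are generated directly at a true
fraction of 0.05. Concentrations beyond ~650 uM at 24 h clip at 1, which
mirrors the loss of linearity reported at high dose; parameter-recovery
tests therefore use the unclipped regime.

Whole plates couple a randomized `build_plate_layout()` (by default 114
genes in triplicate plus 42 negative-control wells on a 384-well plate) to
an `effect_table()` of multiplicative per-gene shifts on the positive
fraction and/or punctum intensity; control wells always use effect 1.
Negative-control wells are treated as exchangeable draws from one null
condition: the original screen used seven distinct negative controls across
its 42 control wells, but their composition is not modelled.

3D stacks plant non-overlapping spherical aggregates with exact voxel
counts (the rasterized ball is trimmed to the target count, and the truth
records the rasterized centroid), over a dim noisy background. Planted
counts are constrained to the detectable range of 10-1000 voxels.

## The screen pipeline

1. **Illumination correction + contrast stretch**
   (`preprocess_nuclei_image()`). A smoothed copy of a nuclei image tracks
   local cell density rather than illumination, so the multiplicative gain
   surface is instead estimated from the field's own point sources: local
   intensity maxima (7x7 max filter; one peak per nucleus, height = gain x
   amplitude) are collected and a quadratic surface is fitted through the
   peak heights. The image is divided by that surface and linearly rescaled
   to [0, 1]; a flat image maps to 0.5 by convention, an all-zero image is
   returned unchanged. On constant-amplitude test fields this removes more
   than 95% of a planted polynomial gradient; on realistic fields the
   residual is bounded below by the per-nucleus amplitude scatter (about
   20% per cell), which no single-field estimator can remove.
2. **Segmentation** (`segment_nuclei()`): global Otsu threshold on the
   preprocessed image, 8-connected component labelling, and a two-sided
   size cutoff (default 20-2000 px) for outliers. The threshold rule is a
   package choice; the original analysis names only "a contrast stretching
   routine" and "a size-based cutoff".
3. **ROIs** (`make_cell_rois()`): each retained nucleus centroid (unweighted
   pixel mean) is dilated into a disk of radius 10 px; contested pixels go
   to the nearest centroid (ties to the lower label), keeping ROIs disjoint
   so per-cell totals are additive. A radius-10 disk holds at most 317
   pixels. Nuclei with solidity below 0.8 are rejected as clumps; an
   optional ROI-variance floor rejects out-of-focus cells (both criteria
   are package choices where the original scripts state only that such
   filters existed, and both are exposed as parameters).
4. **Features** (`subtract_local_background()`, `cell_intensity_features()`):
   the GFP channel is background-corrected by subtracting its grayscale
   opening with a 3 px disk — puncta (narrower than the disk) survive,
   diffuse per-cell signal and any constant pedestal are removed — and each
   ROI yields its average and total corrected intensity.

## Hit calling

For each parameter (average and total intensity) and plate:

* `ks_statistic()` computes the signed two-sample Kolmogorov-Smirnov
  statistic `D = F_well(t*) - F_controls(t*)` at the point maximizing the
  absolute CDF difference over the pooled support. `|D|` is the classical
  two-sample KS statistic; the sign is positive when the well's intensities
  are stochastically smaller (suppressor direction). The statistic the
  original analysis used is described only as "KS-like"; the classical
  signed D is this package's declared reference construction.
* Control wells are compared leave-one-out against the pooled remaining
  controls, so control and gene wells face statistically equivalent
  references. `zscore_plate()` standardizes every well with the median and
  MAD (x 1.4826) of the control statistics — robust location/scale, so a
  contaminated control well cannot inflate the plate scale.
* `monte_carlo_threshold()` calibrates the |z| cutoff for the exact
  decision rule used downstream: each of `n_sim` pseudo-genes draws three
  distinct control wells; each drawn well contributes a bootstrap resample
  of its own cells, whose KS statistic and z-score are recomputed; the
  pseudo-gene's statistic is its second-largest |z| — precisely the order
  statistic that a two-of-three rule thresholds. The cutoff is the
  (1 - alpha) quantile (default alpha 0.001, 5000 pseudo-genes). The
  cell-level bootstrap matters: resampling wells as atoms would cap the
  simulated null at the second-largest observed control |z| and make small
  alpha unreachable; with the bootstrap, held-out null pseudo-genes exceed
  the threshold at below the nominal rate.
* `call_hits()` applies the two-of-three rule (`|z| >` threshold in at
  least 2 replicates, two-sided), annotating direction from the signs of
  the qualifying replicates (suppressor / enhancer / mixed).
  `estimate_error_rates()` scores calls against planted truth, and
  `category_summary()` reports hits as a percentage of screened genes per
  (externally supplied) category; parameter-wise hit sets combine by union
  or intersection via `hit_genes()`.

## The macro-equivalent counters

`count_cells_binary()` and `count_aggregate_positive_cells()` reproduce the
recorded imaging-macro pipeline used for the dose-response experiments:
8-bit conversion (linear min-max rescale — the mapping is a package
choice), mean subtraction (DAPI), rolling-ball background subtraction at
the recorded 0.3 px radius (honoured as configuration; at sub-pixel radius
the background estimate hugs the image and the subtraction is treated as a
no-op), binarization, watershed splitting (DAPI), merging of puncta closer
than one cell radius into one object (closing with a disk of half the cell
radius), and particle counting at size 10-500 px. The recorded
"circularity 1" is read as the non-excluding range [0, 1]. Binarization of
the GFP channel uses an intermeans (IsoData) iteration seeded at the range
midpoint: with a dim diffuse class occupying a nontrivial fraction of
pixels, variance-based rules (Otsu) and mean-seeded iterations place the
cut between background and diffuse signal and would count every wild-type
cell as aggregate-positive; the midpoint-seeded iteration converges to the
fixed point between the dim mass and the bright puncta. `fit_dose_response()`
is an ordinary least-squares line through measured fractions.

## The brain assay

`detect_aggregates_3d()` thresholds a stack (by default at the 99.5th
percentile of its own intensities — an explicit, reproducible stand-in for
the per-image manual threshold of the original assay, overridable with a
numeric threshold), labels suprathreshold voxels by 26-connectivity, and
keeps components of 10-1000 voxels, bounds inclusive (the original text
excludes objects "greater than 1000" and "smaller than 10", which makes
the bounds inclusive). `aggregation_density()` counts objects whose
centroid falls in each of three congruent half-open ROI boxes and divides
the mean per-ROI count by the single-ROI volume in um^3.
`normalize_and_compare()` divides each animal's density by the control
group mean (control mean is exactly 1 by construction) and runs Student's
t-test (two groups) or one-way ANOVA followed by Fisher's LSD — unadjusted
pairwise t-tests on the pooled within-group variance, flagged as such in
the output.

## Problem sizes used by the test suite

The statistical design under test is always the screen's own — 114 genes in
triplicate, 42 control wells, alpha 0.001, two-of-three calling — but
simulated plates in the test suite use down-scaled fields (about 60 cells
of radius 6 px in a 192 px field, 2-3 fields per well) so that a whole
plate's images can be synthesized and analyzed in about a minute; the
dose-response and detection-contrast checks use full-scale fields (400
cells, 1024 px). The brain power analysis uses 30 simulated experiments of
8 animals per group. The suite verifies, among other properties: a fully
null plate yields zero called hits; ten planted suppressors (effect 0.25)
among 114 genes are recovered with no false positives across five seeds;
mutant-like and wild-type-like fields reproduce the >80% / <10% contrast;
and |KS|, ANOVA/LSD and 3D densities match independent oracles exactly.

## What passing tests do and do not show

The generator emulates the statistical structure the pipelines assume:
non-overlapping nuclei, binomial positivity, compact bright puncta over
diffuse signal, smooth multiplicative shading, homogeneous control wells.
Real screens add confounds the generator deliberately omits — cell
clumping and mitosis, focus drift, plate-edge effects, heterogeneous
control behaviour, segmentation-hostile debris — so green tests here
demonstrate correctness of the machinery and its calibration under the
stated model, not performance on any particular real dataset. Photorealistic
PSF simulation, cell motility and dsRNA biochemistry are out of scope by
design.

## Numerical conventions and edge cases

Coordinates are (row, column), 1-based in R; ROI and box membership uses
half-open intervals; ties in nearest-centroid assignment go to the lower
label; KS argmax ties resolve to the first pooled point (only the signed
value at the maximizing point is reported). All randomness derives from a
single seed through named substreams (placement, positivity, rendering,
illumination, noise, layout, Monte-Carlo), so any artefact can be
regenerated bit-identically from its logged configuration. Degenerate
inputs have defined behaviour: empty fields segment to zero cells, an
all-zero image preprocesses to itself, a zero-cell well is excluded with a
warning, a degenerate control null (zero MAD) and a zero-cell denominator
are errors, and a detection threshold above the stack maximum yields zero
objects.
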