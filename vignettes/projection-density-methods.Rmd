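---
title: "Quantifying projection density and projection-neuron composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying projection density and projection-neuron composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projdense)
```

## The scientific problem

A cortical population can innervate several target regions with very
different strength. Given high-magnification confocal stacks of labeled
axons captured in two targets — here the nucleus accumbens (NAc) and the
ventral tegmental area (VTA) of the mouse, innervated by medial prefrontal
cortex (mPFC) — the question is how strongly each target is innervated and
whether a single per-animal number can express target preference.

`projdense` covers the three quantitative layers of such a study:

1. **Axon density from image stacks.** Total axon length per stack is
   measured by segmentation and 3D skeletonization; the *relative axon
   density* is

   \[ \mathrm{RAD} = \frac{\text{total axon length (mm)}}
                          {\text{total analyzed volume (mm}^3)} \]

   summed over all stacks of one region in one animal, and the per-animal
   preference index is \(\mathrm{RAD_{VTA}} / \mathrm{RAD_{NAc}}\)
   (1 = equal innervation).
2. **Cell-count statistics.** Tables of retrogradely labeled neurons
   (one row per counted cell with animal, Bregma level, subregion, layer,
   tracer and marker status) are summarized into anteroposterior /
   subregional / laminar distributions, marker colabeling proportions, and
   double-labeling overlap ratios, all as per-animal percentages reported
   mean ± SD.
3. **Group comparison.** Per-animal indices are compared across groups
   with a one-way ANOVA followed by Fisher's LSD post hoc test, preceded
   by a Levene homogeneity diagnostic.

## Axon length from a stack

The acquisition-side contract is an `image_stack`: a `(z, y, x)` intensity
grid with physical voxel spacing in micrometers. Confocal stacks are
anisotropic; the default spacing `(0.27, 0.2, 0.2)` µm mirrors a ×63 oil
objective with a 0.27 µm axial step. The in-plane pixel size of such
acquisitions is instrument-dependent; 0.2 µm is this package's default,
not a measured constant.

The measurement chain is:

* `binarize_stack()` — optional in-plane Gaussian pre-smoothing (default
  σ = 1 voxel), a global threshold (Otsu by default, or fixed), and
  removal of 26-connected components below `min_object_vox` (default 27
  voxels ≈ a 3×3×3 speck). Nothing in the upstream acquisition protocol
  fixes these choices, so they are explicit arguments and are echoed into
  the provenance attribute of every measurement. A constant stack yields
  an empty mask by convention.
* `skeletonize_stack()` — topology-preserving 3D thinning: iterative
  directional removal of *simple* border voxels (a voxel is simple when
  its 26-neighborhood foreground forms one 26-component and its
  18-neighborhood background forms one 6-component touching a face
  neighbor), with line endpoints preserved. Thinning operates on the
  native anisotropic grid; no resampling is performed, so no
  interpolation artifacts enter the geometry.
* `skeleton_length()` — the skeleton graph connects every pair of
  26-adjacent skeleton voxels exactly once, and the total length is the
  sum of anisotropic edge lengths
  \(\sqrt{(\Delta z\,d_z)^2 + (\Delta y\,d_y)^2 + (\Delta x\,d_x)^2}\),
  reported in mm. Counting each unordered adjacency once is what makes
  the measure well defined on diagonal chains.

`quantify_stack()` composes the three steps and attaches the analyzed
volume: an explicit `roi_spec()` (ROI area × slice count × axial step)
when one is given — matching how such acquisitions are normally reported —
otherwise the full physical stack extent.

### Known biases and degenerate inputs

Digital skeleton length has two systematic error sources: staircase
overestimation of oblique curves (bounded by the voxel geometry, a few
percent) and end/spur effects from blurred tube ends. Short corner spurs
can survive thinning because endpoints are protected; they are small
relative to the curve length at realistic tube radii. The parameter
recovery test below quantifies the net effect. Degenerate cases are
defined, not errors: an empty mask gives an empty graph and zero length;
a single voxel gives one node and no edges; a fixed threshold outside the
intensity range saturates to a full or empty mask with a warning.

## The synthetic phantom

Because raw stacks from the motivating study are not redistributable, the
package generates its own validation data. `axon_phantom_spec()` /
`generate_axon_stack()` draw piecewise-linear random-walk centerlines
(1 µm steps, turn angle uniform within `tortuosity_deg`, default 30°),
rasterize them as tubes (a voxel is foreground when its center is within
`tube_radius_um` of a centerline, distances in physical µm), convolve with
an anisotropic Gaussian PSF (default σ = (0.6, 0.25, 0.25) µm,
axial > lateral as in confocal optics), add a background offset and
Poisson shot noise. Defaults: 20 axons of 20–200 µm at a peak/background
ratio of 10, in a stack of ≈ 10⁻⁴ mm³ — the scale of a 63× field of view.
The exact centerlines are returned, so total ground-truth length is known
to machine precision; axons are clipped at the stack border and the
clipped length is recorded, since that is all any in-stack measurement
could see.

Each axon uses its own seeded RNG substream, so increasing `n_axons`
extends a phantom without redrawing earlier axons — which is what makes
"more axons never means less length" a testable invariant.

What the phantom does *not* emulate: depth-dependent attenuation,
bleed-through, immunolabeling variability, non-axonal structures, and
tissue deformation. Passing recovery tests therefore validate the
geometry and the measurement chain, not robustness to every property of
real tissue.

The test suite demands median absolute length-recovery error ≤ 15 % over
20 phantoms (4 axons of 15–35 µm in 32×128×128 stacks — sizes chosen to
keep the whole suite fast at desk scale); observed error is ≈ 9–10 %,
dominated by staircase overestimation.

## Cell-count analytics

`read_cell_table()` enforces the interchange format (`animal, bregma_mm,
subregion, layer, tracer_nac, tracer_vta, calb1, ctip2, foxp2`) with
closed category sets for subregion and layer and tri-state marker flags
(`1 / 0 / NA` = positive / negative / not assessed). The manual-counting
contract — a cell counts only once, confirmed with a visible nucleus — is
an input assumption the software cannot re-verify.

* `assign_ap_bin()` maps Bregma levels to the six standard reporting bins
  (`>2.80` … `<1.42` mm). Bin edges are printed to 2 decimals with both
  endpoints inclusive; values are rounded to 2 decimals before binning so
  every real number lands in exactly one bin.
* `distribution_table()` computes per-animal stratum percentages (of the
  animal's population total — so they sum to 100 per animal), pooled
  counts, and mean ± SD across animals.
* `colabel_proportions()` computes, per layer group and in total, the
  percentage of tracer-labeled cells positive for a marker among cells on
  which that marker was assessed. **Suppression rule:** a row is reported
  as `NA`/suppressed when its pooled marker-positive count is below 10 or
  any per-animal denominator is below 10. This is the convention of not
  quoting percentages from tiny counts; the pooled-numerator clause is
  required to reproduce every suppressed cell of the reference tables
  (one suppressed row there has large denominators but only 7 positive
  cells).
* `overlap_statistics()` splits cells into single-NAc, single-VTA and
  double-labeled, and reports `double/VTA`, `double/NAc` and
  `double/total` per animal. For cell tables, `total` is the union count
  (singles + doubles). Published tables sometimes carry their own total
  column computed under a different convention; `overlap_from_counts()`
  therefore accepts explicit totals, and the packaged reference fixture
  uses the totals as printed.

## Group statistics

`mean_sd()` is the sample (n−1) standard deviation throughout — the
choice is verified by exact reproduction of more than ten published SDs
from per-animal values. `one_way_anova()` fits the standard one-way
decomposition via `lm()`; a zero-residual fit with unequal means reports
`F = Inf, p = 0` with a `degenerate` flag rather than a numerical error.
`homogeneity_test()` is the mean-centered Levene test — an ANOVA on
absolute deviations from group means, built on the package's own ANOVA so
the all-constant case degrades to statistic 0, p 1. It is reported as a
diagnostic only (the reference analysis protocol names a homogeneity
check but not a test; Levene is the common default). `lsd_posthoc()` is
Fisher's LSD: pooled-MSE t tests on the ANOVA's within degrees of
freedom, two-sided and *unadjusted* — that is the definition of the
procedure, so no multiplicity correction is applied. Its per-comparison
type-I error under a global null (4 groups × 3, 10,000 replicates) is
checked to sit within one percentage point of the nominal 5 %.

## Reproduction of the reference dataset

The per-animal counts, lengths, volumes and densities of the motivating
dataset are shipped as plain-CSV fixtures (`load_reference_counts()`),
and `reproduce_printed_results()` recomputes every summary through the
regular analysis functions — counts are expanded to one row per cell and
fed through `distribution_table()` / `colabel_proportions()`, overlap
ratios go through `overlap_from_counts()`, and the relative-density
groups through `mean_sd()`, `one_way_anova()` and `lsd_posthoc()`.

Two numerical caveats, both consequences of working from rounded printed
inputs, are worth recording:

* The published omnibus F (55.56) was evidently computed from unrounded
  per-animal ratios. From the printed ratios the package obtains
  F(3, 8) = 55.53 (p = 1.06 × 10⁻⁵) — the same inference and the same
  post hoc pattern; the third significant digit of F is not recoverable
  from printed data.
* The printed per-animal ratio column is rounded to ~2 significant
  figures; group means/SDs at full printed rounding (e.g. 0.88 ± 0.49)
  are recovered by recomputing each animal's ratio from the printed
  density columns via `rad_ratio()`.

Also recorded: in the reference density table, the printed per-animal
densities are consistent with the two regions' volume columns being
interchanged relative to the length columns. The fixtures store all
columns exactly as printed, and density-derived statistics use the
printed density and ratio columns directly; nothing is silently
"corrected".

## Pipeline and interfaces

`run_pipeline()` executes `simulate → quantify → cellstats → stats →
reproduce` from a validated configuration (list or YAML), writes tidy
CSVs plus a `provenance.yml` echo of the configuration, and fails before
producing any output when the configuration is inconsistent. A thin
command-line wrapper with the same subcommands ships at
`inst/scripts/projdense.R`; the R functions are the primary interface.

Stacks are exchanged as multi-page TIFF with a YAML sidecar carrying the
voxel spacing (TIFF tags cannot express the axial step) and the intensity
scale; reading a stack with no spacing information fails rather than
assuming isotropy.

## Limitations

* Global thresholding presumes reasonably uniform background; stacks with
  strong gradients need pre-correction upstream.
* Skeleton length is a centerline measure: boutons, varicosities and
  axon calibers are out of scope, as is distinguishing axons from
  dendrites or cell bodies.
* The suppression and total-column conventions above were chosen to
  reproduce the reference tables exactly; other datasets may follow
  different reporting conventions and should set the corresponding
  arguments explicitly.
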