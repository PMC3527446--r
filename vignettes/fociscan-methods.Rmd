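---
title: "Quantifying cytoplasmic foci by prototype correlation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic foci by prototype correlation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stress granules (SGs), processing bodies (PBs) and related mRNA-silencing
foci are micrometre-scale cytoplasmic aggregates that form and dissolve with
cell physiology. Experiments on their regulation are read out from
two-channel fluorescence micrographs - a DAPI nuclear channel and a foci
channel (FISH against polyadenylated RNA, or immunofluorescence against a
marker such as eIF3&eta; or DCP1a) - by counting, per cell, how many foci
are present, how large they are, and how the percentage of focus-positive
cells shifts between treatments. Manual scoring of such images is slow and
operator-dependent; high-content screens make it infeasible. `fociscan`
automates the readout: cells are segmented from the nuclear channel,
foci are detected by template matching against a bank of example granules,
and per-cell statistics, inter-object distances and control-normalised
screen scores are computed from the detections.

## The pipeline

1. **Preprocessing.** Intensities are clipped to a cap (default 255: in the
   source image regime well under 0.1% of pixels exceed it; the clipped
   fraction is logged so other regimes are visible). The nuclear channel is
   contrast-stretched between its 1% and 99% quantiles.
2. **Nuclear mask.** Pixels at or above 60% of the stretched nuclear
   maximum are nuclei; interior holes (nucleoli) are filled. Each connected
   component is one candidate nucleus.
3. **Cell segmentation.** The foci channel is Wiener-denoised, multiplied
   by a gain (default 2, compensating faint cytoplasmic staining) and
   complemented, so stained cell material lies low and empty background
   high; nuclear pixels are forced to zero. A marker-controlled watershed
   (Meyer flooding in topographic order, 8-connected) grows one catchment
   basin per nucleus; ridge pixels separate cells. Cells whose stained
   foreground area is below 30 um^2 (partially attached or unhealthy cells)
   are excluded.
4. **Detection.** Normalized 2-D cross-correlation (sliding-window Pearson)
   is computed between the clipped foci channel and each prototype - a
   small patch holding one example granule *plus a margin of surrounding
   cytoplasm*, which anchors local contrast and is what makes strict
   thresholds workable. Pixels whose correlation strictly exceeds the
   prototype's similarity threshold (ST) become seeds. A second pass over
   the unsharp-filtered image recovers the minority of weakly stained foci;
   with 8 prototypes this is the classic 16-correlation sweep per field.
   Seeds inside the nucleus (abundant nuclear polyadenylated RNA) and in
   extracellular regions are removed.
5. **Merging and counting.** Each seed is dilated to a centred 3x3 square
   (the size of a small focus at 63x / 512 px); squares of seeds belonging
   to the same focus fuse, and each 8-connected component becomes one
   counted object carrying the set of prototypes that hit it. The
   representative point is the centroid snapped to the nearest in-object
   pixel - a deterministic, order-free replacement for the morphological
   shrink operator.
6. **Quantification.** Each object is assigned to the basin under its
   representative point; a cell with two or more foci is *positive*. Field
   summaries report cell counts, focus counts, percent positive cells and
   mean foci per positive cell (over positive cells only). Distances
   between object classes (e.g. synapses and synaptic foci) are measured by
   the Euclidean distance transform of the focus mask, sampled at target
   points - point-to-object distances, not centroid-to-centroid.
7. **Screening.** Fields are pooled per well by summed counts (a
   cell-weighted percentage, not a mean of field percentages, since fields
   differ in cell number). The screen score of a well is its percent
   positive divided by the mean percent positive of the untreated control
   wells of the same plate.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `preprocessing$cap` | 255 | intensity | clip ceiling; data-dependent, logged |
| `preprocessing$stretch_low/high` | 0.01 / 0.99 | quantile | contrast stretch bounds |
| `preprocessing$wiener_window` | 3 | px | adaptive denoise window (smallest; granule scale) |
| `preprocessing$unsharp_alpha` | 0.2 | - | unsharp kernel shape |
| `preprocessing$gain` | 2 | - | cytoplasm gain before elevation building |
| `segmentation$threshold_frac` | 0.6 | fraction | nuclear threshold vs stretched maximum |
| `segmentation$min_cell_area_um2` | 30 | um^2 | small-cell exclusion |
| `segmentation$foreground_frac` | 0.05 | fraction | stained-material threshold (extracellular rule) |
| `detection$st` | 0.89/0.88/0.80/0.88/0.86/0.86/0.92/0.85 | correlation | per-prototype similarity thresholds |
| `detection$min_focus_area_um2` | 0 (off) | um^2 | optional small-focus filter (0.2 for synaptic foci work) |
| `quantification$min_foci_for_positive` | 2 | count | positivity rule |
| `quantification$proximity_radius_um` | 0.5 | um | proximity radius for distance analyses |
| `quantification$size_reliability_width_px` | 6 | px | minimum width for trustworthy sizes |

Coordinates are 1-based `(row, col)` in R convention; areas are reported in
pixels and in um^2 via the user-supplied pixel size (image metadata rarely
carries a trustworthy value, so it is explicit in the configuration).

## The default prototype bank

Eight prototypes are extracted from a deterministic, noise-free synthetic
reference field and cover the four recurring granule morphologies: round
granules at three sizes, one dense uniform-intensity body, elliptical
granules in both axis orientations, and two bright-cored granules. Each
slot carries its own ST; the strictest values sit on large high-contrast
morphologies, the laxest (0.80) on the small round slot whose correlations
are most attenuated by noise. Rotated variants can be generated
(`with_rotations()`) and are assessed at the ST of their parent, but are
disabled by default: on isotropic granules they add no objects beyond the
unrotated bank, so they only multiply the number of correlations.

Strict thresholds kill false positives at the cost of per-prototype
sensitivity; the union over a morphologically diverse bank restores it.
Both halves of that trade-off are exercised in the acceptance tests
(single-prototype recall is far below full-bank recall, and recall is
monotone non-increasing in ST).

## Measuring focus size

The merged-object pixel count is the detector's native size measure and is
reported on every object, with a reliability flag: sizes are only
trustworthy when the object's bounding box exceeds 6 px, so size studies
belong at higher magnification or resolution. The pixel count, however,
tracks how far the correlation with the best prototype stays above
threshold, which compresses large foci relative to small ones. For
dedicated size-change analyses the package therefore re-measures each
detected focus from the image (`measure_focus_sizes()`): a local window is
smoothed 3x3, the background is taken from the window ring (a second pass
re-sizes the window from the measured radius so the ring sits clear of the
focus tail), and the focus is re-segmented at half of the peak-over-
background. Detection identity is untouched; only the size fields change.
For sizing runs the detector uses a dense geometric ladder of round
prototypes (`size_ladder_bank()`, ~12% steps, margins proportional to the
radius) at one moderate ST of 0.8, mirroring how size-oriented analyses of
processing bodies re-tune to a single common threshold.

## The synthetic generator

`synthetic_spec()` / `generate_field()` emulate the target image regime so
that every pipeline stage is testable without any external data: bright
nuclei (mean intensity about 200 on the 8-bit scale) with mild
ellipticity; faint uniform cytoplasm (level 30 over background 5); a
nuclear polyadenylated-RNA signal in the foci channel including two bright
intranuclear speckles per cell, planted deliberately so that the
nuclear-seed elimination stage has real work to do; granules rendered as
anisotropic Gaussian profiles with optional brighter cores, or as dense
uniform-intensity disks, with peaks 110-215 over cytoplasm; additive
Gaussian noise (sigma 8, i.e. granule signal-to-noise of at least 13).
Defaults: 512 px fields at 0.2 um/px, 15 cells of radius 6-9 um, half of
them positive with 2-6 granules each, negative cells carrying at most one
granule - the regime of stressed insect-cell fields where roughly half the
cells form granules and positive cells average 3-5 of them.

Ground truth records every cell footprint, nucleus and granule (centre,
axes, and the planted area, defined as the rendered above-half-maximum
pixel count). `evaluate_detection()` matches detections to planted granules
greedily one-to-one within a radius (default 1 um) and reports precision
and recall.

What the generator does **not** emulate: optics (no point-spread function -
the smooth Gaussian granule is an idealisation; real confocal sizes are
PSF-broadened and size comparisons across magnifications need care),
uneven illumination, autofluorescence texture, touching or overlapping
cells, and granule orientation off the pixel axes. Passing tests on this
material therefore demonstrate the correctness and calibration of the
algorithmic chain, not robustness to every real-world artefact.

## Study conditions used by the benchmarks

- *Detection benchmark*: 20 default fields (~300 cells, ~550 granules).
- *Watershed contract*: 100 fields of 256 px with 5 cells each.
- *Screening benchmark*: one plate of 12 wells (six untreated controls,
  three irrelevant-knockdown wells at the control positive fraction 0.45,
  three knockdown wells planted at 0.6x that fraction), 20 fields of 10
  cells per well; scores are means over the three wells of a treatment.
  The control positive fraction matches the 37-47% range of untreated
  stressed-plate controls.
- *Size-change benchmark*: paired basal/stressed populations at
  0.05 um/px, two large cells per field, five fields per group; the
  stressed group re-uses the basal seeds with granule radii scaled by
  sqrt(3.5), so the planted area ratio is 3.5 by construction (common
  random numbers make the comparison paired rather than two independent
  draws whose realised ratio would wander several percent).

These sizes keep the full suite within a desktop-scale run while leaving
enough events (hundreds of cells and granules) for the rates to be stable.

## Numerical and design choices

- **Correlation engine.** The production path computes the cross term by
  FFT convolution and window moments by summed-area tables over the
  globally centred image (centring is what keeps the `E[x^2]-E[x]^2` form
  safe); a direct two-pass C++ implementation is kept as an independent
  route and the test suite pins both against a plain-R sliding `cor()`
  oracle to 1e-10. Border positions where the template does not fit are
  invalid (`NA`), never padded.
- **Seeds** are every supra-threshold pixel (strict `>`), not local maxima;
  the 3x3 dilation merge absorbs the resulting clusters. Merging uses
  8-connectivity, so squares touching even at a corner fuse; two seeds
  merge up to Chebyshev distance 3 and are always separate from distance 4.
- **Watershed** is Meyer's flooding with a lowest-elevation priority queue,
  FIFO tie-break for determinism, 8-connectivity, and explicit watershed
  lines (label 0). Markers are imposed as minima, which prevents
  over-segmentation from noise minima.
- **Detection channel.** Gain and Wiener denoising serve border
  identification; correlation runs on the clipped, unscaled channel
  (configurable via `detection$use_preprocessed`). NCC is invariant to
  affine intensity maps, so the gain would be a no-op and the denoiser
  would only blur the patterns being matched.
- **Extracellular rule.** Watershed basins tessellate the whole field, so
  "extracellular" is defined by a stained-material foreground mask
  (>= 5% of the stretched foci maximum, specks removed, holes filled);
  `foreground_frac = 0` disables the filter.
- **The 30 um^2 cell filter** is applied to stained-foreground area, not
  raw basin area, because basins always tile the full image. Cells touching
  the field border are kept but flagged.
- **Degenerate inputs.** Constant images pass through the stretch with a
  message; empty nuclear masks flag the field, which is skipped with a
  warning while other fields continue; zero-cell wells are flagged invalid
  and excluded from control means.
- **Resampling** is separable Keys cubic (a = -0.5) with kernel widening on
  downscale (antialiasing); the pixel size rescales so physical field size
  is preserved exactly.
- **Command-line interface.** The package functions are the primary
  interface; a thin `inst/scripts/fociscan` Rscript exposes `synth`, `run`
  and `screen` subcommands for shell use. The remaining pipeline stages
  are reachable as exported functions rather than separate subcommands.

## Known limitations

- Touching nuclei are not declumped; each connected nuclear component is
  one marker, so confluent fields under-segment.
- Sizes below the 6 px reliability width are reported but flagged; at
  typical screen resolution most single-seed objects are below it.
- The screen score is the plain control-normalised ratio; no plate-effect
  correction (B-score, Z') or hit-calling statistics are provided.
- The correlation detector deliberately omits Gaussian/LoG matched
  filtering and sub-pixel localisation; prototypes from example images
  outperformed synthetic Gaussian filters in the source experiments, and
  counting does not need sub-pixel accuracy.
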