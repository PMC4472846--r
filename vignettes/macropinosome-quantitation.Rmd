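---
title: "Quantifying macropinocytosis from dextran-uptake images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macropinocytosis from dextran-uptake images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

Macropinocytosis is actin-driven bulk fluid uptake: stimulated cells ruffle
their membranes and trap extracellular fluid in large vacuoles
(macropinosomes, 0.2–5 µm across). Pulsing adherent cells with a
fluid-phase marker — fluorescent 10 kDa dextran — for five minutes labels
exactly these nascent structures; counting the labelled structures per cell
then measures macropinocytic activity, and drug or knock-down effects
appear as fold changes between conditions.

`macroquant` implements the image-analysis half of that assay as a
scriptable batch pipeline. For every multi-channel confocal z-stack it:

1. splits the channels (dextran, optional GFP reporter, DAPI);
2. collapses each channel by **maximum-intensity projection**;
3. converts to **8-bit** with one linear range for the whole experiment;
4. removes smooth background with a **rolling ball** — the grayscale
   opening with a ball-shaped structuring element of height profile
   $h(\Delta y,\Delta x)=\sqrt{r^2-\Delta y^2-\Delta x^2}$;
5. thresholds to a binary mask of dextran-positive structures and, if
   enabled, applies a **distance-transform watershed** to separate touching
   structures;
6. optionally restricts the mask to GFP-positive cell footprints (the
   GFP channel is projected and converted but *not* ball-subtracted: a
   cell footprint is wider than the macropinosome-scale ball, so the
   opening would classify the footprint itself as background and erase
   the very signal the mask is built from);
7. runs **particle analysis** with the calibrated size filter
   0.2–20.0 µm² (equivalent-circle diameters 0.5–5.0 µm), measuring area,
   equivalent diameter, centroid and integrated density per particle;
8. segments and counts **DAPI nuclei** the same way (threshold, hole fill,
   watershed, area floor) and reports macropinosomes **per cell** and
   **per 100 cells**, aggregated per condition as mean ± SEM over
   replicates (sample SD / √n).

One parameter set governs a whole experiment; the schema has no per-image
overrides, mirroring the requirement that all samples of an experiment be
acquired and processed identically. Every resolved parameter (conversion
range, rolling-ball radius, per-channel threshold cutoffs, watershed
settings) is written to `manifest.json`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rolling_ball_radius_px` | `ceil(3 × 5 µm / pixel size)` | px | 3× the largest object of interest: the ball must not fit inside a macropinosome |
| `size_filter` | [0.2, 20.0], inclusive | µm² | the published macropinosome definition (0.5–5 µm equivalent diameter) |
| `dextran_threshold` | robust background, k = 6 | – | see below |
| `dapi_threshold`, `gfp_threshold` | Otsu | – | nuclei/cells are large, bright, bimodal — Otsu's natural regime |
| `watershed$min_peak_separation_px` | `ceil(0.5 µm / pixel size)` | px | distance-map peaks closer than the smallest real object are one object |
| `watershed$tolerance` | 0.2 | px | peaks shallower than this merge; digitised single disks/ellipses stay intact down to 0.1 |
| `min_nucleus_area_um2` | 30 | µm² | below typical HEK293 nuclear cross-sections, above organelle-scale DAPI speckle; set per cell line |
| `min_cell_area_um2` | 50 | µm² | GFP debris floor |
| `conversion_mode` | `batch_range` | – | one linear 8-bit map per experiment, resolved in a first pass |

### The dextran threshold

The published workflow leaves the threshold to the user ("optimize before
batch processing"). Automating that choice is the one place this package
departs from the obvious default:

* **Otsu** maximises between-class variance. On a background-subtracted
  punctate image the foreground is < 2 % of pixels with roughly equal peak
  brightness, and the criterion settles at ~0.6–0.7 of the structure peak.
  A 0.5–0.7 µm macropinosome then leaves fewer than three pixels above
  threshold and is dropped by the 0.2 µm² area floor: measured on
  synthetic fields, pooled F1 0.877 with a 22 % count deficit.
* The default is therefore a **noise-referenced cutoff**:
  median + k·1.4826·leftMAD of the corrected image, where *leftMAD* is the
  median absolute deviation of the pixels at or below the median. The
  one-sided estimator matters: structures only populate the upper tail, so
  the left half is pure residual noise and the cutoff becomes independent
  of how much foreground a field carries and of the 8-bit conversion
  scale. (A two-sided MAD inflated with confounder tails made the cutoff,
  in physical photon units, drift with field size and condition — sparse
  drug-treated fields then flooded with sub-resolution false positives.)
* **k = 6** was fixed by a specificity rule evaluated on
  macropinosome-free synthetic fields: the smallest k with fewer than one
  false count per 100 cells (measured 5.0 / 2.35 / 1.18 / 0.59 false
  counts per 100 cells at k = 4.5 / 5 / 5.5 / 6). False counts add the
  same absolute offset to every condition, so they bias fold changes
  asymmetrically — specificity protects the assay's headline readout.
* On a noiseless image a noise-referenced cutoff is undefined (leftMAD
  = 0); the method then falls back to Otsu, and to an empty mask for a
  constant image.

Otsu and fixed thresholds remain available per channel
(`segmentation$*_threshold$method`). Within a batch, Otsu and
robust-background cutoffs are resolved once per channel role from the
pooled histogram of all corrected images, never per image.

### Watershed

The splitter computes the exact Euclidean distance transform, finds its
significant maxima (merging any maximum whose flooded region, at a depth
`tolerance` below its peak, reaches a higher claimed region — an h-maxima
criterion), suppresses markers closer than `min_peak_separation_px`, and
floods the negated distance map with Meyer's algorithm. Divide lines are
single-pixel and removed from the mask; no pixel is ever added and
components are never merged.

## The synthetic world

`generate_scene()`/`render_stack()` emulate the assay's imaging conditions
so that every pipeline stage can be validated against ground truth:
512×512 px at 0.3 µm/px, 11 z-slices at 0.5 µm; elliptical cells
(semi-axes 5–10 µm) at a target confluency with one nucleus each
(semi-axes 4–7 µm); per-cell Poisson(5) macropinosomes with log-uniform
diameters over [0.5, 5] µm, placed in the outer 30 % of the cell radius
with **3-D non-overlap** (vacuoles are membrane-bound; rejection sampling
with bounded retries, re-drawing the diameter after repeated collisions);
Poisson(20) sub-resolution vesicle confounders (0.1–0.2 µm) per cell; a
low-order polynomial illumination gradient; Poisson photon noise plus
Gaussian read noise (σ = 2). Rendered structure peaks are scaled so the
post-blur peak over the local background equals `snr` (default 10) times
the local noise SD, with a 0.35 µm optical-section half-thickness so
sub-slice structures still appear in one plane. Confounders are dimmer in
proportion to diameter — equal luminal dextran concentration means peak
brightness tracks the axial path length.

Cell placement uses a jittered hexagonal lattice with axes adapted to the
pitch, because sequential rejection placement of non-overlapping ellipses
jams near ~55 % coverage and cannot reach the 75 % confluency the assay
tolerates; one calibration pass rescales axes until the rendered footprint
fraction matches the request. Crowded fields therefore contain smaller
cells, as in culture.

What the generator does **not** emulate: photobleaching, stage drift,
axial PSF asymmetry, autofluorescence texture, dextran in maturing
endolysosomes, cell-to-cell brightness variability. A green synthetic test
therefore establishes that the *algorithmic chain* is faithful and
calibrated, not that any particular microscope will match it.

## Measured limits (what the tests do and do not establish)

Two boundaries of the method show up quantitatively in the synthetic
world, and both are properties of the assay class rather than bugs:

* **Projection occlusion.** At 5 macropinosomes/cell, 40 % of structures
  have another structure's projected footprint within 0.3 µm
  (z-separated; the maximum projection merges them). With noise removed
  and the threshold swept, pooled recall never exceeds ~0.84 — an
  EDT-watershed ceiling. The pooled detected-vs-truth count discrepancy
  on 20 default fields is ~0.17–0.21, the same order as the ~13 %
  manual-vs-automated difference reported for the original protocol.
  Because the dense condition undercounts more, recovered fold changes
  between a control (4.5/cell) and an EIPA-like condition (1.0/cell) land
  near 4.2–4.3 rather than 4.5.
* **Small-structure/confounder overlap.** A 0.5–0.7 µm macropinosome
  needs the cutoff below ~½ of its peak to leave ≥ 3 pixels at 0.3 µm/px,
  but the brightest 0.2 µm confounders peak at ~0.4× the macropinosome
  peak. Any threshold therefore either truncates the smallest decade of
  the size distribution (uniformly across conditions — the losses cancel
  in fold ratios) or admits confounder-cluster false positives that
  corrupt sparse conditions. The default operating point chooses
  specificity.

## Numerical conventions

* Axis order (z, channel, y, x); y down, x right; 0-based pixel
  coordinates; half-open bounding boxes.
* 8-bit conversion rounds half-up after clipping.
* Thresholds are inclusive (`intensity >= cutoff`); size-filter bounds are
  inclusive at both ends.
* Foreground connectivity 8, background 4.
* Border-touching particles are kept and flagged
  (`exclude_border_particles` opts out); macropinosomes concentrate at
  cell peripheries, which may abut the field edge.
* Hole filling applies to cell and nucleus masks, not to the
  macropinosome mask (dextran rings must not be inflated).
* A field with zero nuclei is flagged invalid and excluded from condition
  means; a replicate with fewer than 200 cells raises `under_sampled`.
* All randomness is seeded; identical configuration and seed give
  bit-identical CSV outputs. Scene generation restores the caller's RNG
  state.

## Known limitations

* Quantitation is 2-D on the projection (as published); structures hidden
  behind others in z are not separable by any mask-based splitter.
* Nucleus counts carry a border-clipping bias (footprints cut by the
  field edge can fall under the area floor). The bias is identical across
  conditions and cancels in ratios; absolute per-100-cell levels are
  correspondingly conservative.
* The baseline TIFF reader/writer covers uncompressed grayscale/RGB
  material (plus ImageJ-style hyperstack and OME physical-size metadata);
  compressed or exotic TIFFs should be converted upstream.
* ImageJ's rolling ball is a shrink-and-interpolate approximation; this
  package computes the exact morphological opening, so backgrounds agree
  with the definition, not bit-for-bit with ImageJ.
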