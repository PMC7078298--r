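---
title: "Quantifying retinal microglial activation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microglial activation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gliaquant` quantifies microglial activation in retinal whole-mount
fluorescence microscopy. Microglia tile the healthy retina as a regular
mosaic of ramified cells; upon activation (for example after an ocular
hypertension insult) they proliferate and migrate, their somata enlarge,
their process arbors retract, they extend vertical processes between the
outer plexiform layer (OPL) and the photoreceptor outer segments (OS),
and resident-microglia markers such as P2RY12 are down-regulated. The
package implements the standard measurement battery for these signs on
20x fields of 0.1502 mm^2, together with a synthetic whole-mount
generator that makes every stage testable against exact ground truth.

```{r}
library(gliaquant)
```

## The cell-counting model

Counting Iba-1+ cells in the plexiform layers uses a four-stage chain,
each stage a pure function:

1. **Normalisation.** The maximum-intensity z-projection is divided by
   its brightest pixel, mapping the field to [0, 1]. This makes the
   chain invariant to global brightness: `count_cells(c * img)` equals
   `count_cells(img)` for any positive scale `c`.
2. **Thresholding.** Values strictly below a fraction of the per-image
   maximum (default 0.2) are zeroed; a value exactly at the threshold is
   kept. The comparison is deliberately `>=`.
3. **Segmentation.** The retained signal is split into 8-connected
   components; components smaller than `min_segment_px` (default 5,
   disableable with 1) are discarded as noise specks. Each surviving
   segment contributes its unweighted centre of mass, in micrometres.
4. **Deduplication.** A ramified cell can fragment into several
   segments, so centroids closer than `min_distance_um` are merged by
   single-linkage clustering with a strict `<` rule: two centroids at
   exactly the minimum distance remain distinct cells. A merged
   cluster's representative is the arithmetic mean of its members.

The minimum distance is the one tunable whose value is not dictated by
the protocol; the default of 25 um is roughly one soma diameter plus a
margin and is echoed into every result so reports always carry it.
Counts are expressed per standard 0.1502 mm^2 field.

Counting operates on the maximum projection of the stack rather than
per z-plane; in the whole-mount setting one stack is one layer of one
field, and layer identity is metadata. A mean projection is available
behind the `method` argument of `max_project()` for denser material.

`count_spots()` is the automated stand-in for interactive point counting
of the sparse, irregular OS cells: the same chain with a smaller minimum
segment (3 px) and a tighter merge radius (15 um). Vertical processes
are counted the same way on the OPL-OS interface plane, at punctum scale
(2 px, 8 um).

## Morphometry

* **Area fraction (Iba1-RA).** In the nerve fibre/ganglion-cell layer
  individual cells cannot be resolved, so the labelled fraction of the
  field is reported instead: the same normalise-and-threshold rule,
  then `sum(mask) / length(mask)`. An Otsu threshold is available as an
  alternative (`method = "otsu"`), and the method used is recorded on
  the result.
* **Soma area.** Two pathways, recorded per result: traced contours
  (ordered polygon vertices, shoelace formula — the analyst pathway) and
  an automated pathway that isolates soma cores by thresholding at
  `core_frac` (default 0.55) of the per-image maximum. Somata are
  substantially brighter than processes, so cores separate cleanly even
  where arbors of neighbouring cells touch.
* **Arbor area.** The hand-drawn polygon through the most distal process
  tips is automated as the convex hull of skeleton endpoints: the cell
  mask is thinned (Zhang-Suen), endpoints are skeleton pixels with
  exactly one neighbour, and the hull area is computed by shoelace over
  `chull()` vertices. The hull necessarily contains the soma and can
  overestimate strongly concave arbors; this bias is deliberate
  (deterministic, oracle-checkable) and documented. Optional spur
  pruning by traced branch length exists but is off by default: thinning
  of disc-plus-stroke shapes produces clean endpoints, while staircase
  junction artefacts can make length tracing cut real branches short.

Fewer than three tips, or collinear tips, give arbor area 0 with a
degenerate flag rather than an error. In whole-field mode
(`arbor_areas_field()`) only cells whose thresholded component contains
exactly one deduplicated cell are measured, mirroring the practice of
measuring well-isolated cells; the pipeline measures up to 16 cells per
field by default, echoing protocols that measure tens of cells per
retina.

## Intensity

P2RY12 expression is summarised as Image Average Intensity: the mean of
all green-channel pixels divided by 255 and expressed in percent. The
denominator is the whole image — no cell mask — because the measure is
defined that way; a mask-restricted variant sits behind the `mask`
argument for sensitivity analysis. 16-bit inputs are rescaled by 1/257
with a message so percentages stay on the 8-bit scale. Summaries report
mean, SD (n−1 denominator) and n per layer x group x day; singleton
groups get SD 0 plus an explicit flag.

## Statistics

The comparison scheme mirrors the conventions of this literature:
Wilcoxon signed-rank for paired eyes (lasered vs contralateral of the
same animal), Mann-Whitney U for independent groups (either eye class vs
naive animals), and one-way ANOVA with Bonferroni-corrected pairwise
contrasts across time points and across the four retinal zones. All
tests are two-sided at alpha = 0.05.

Exact p-values are used whenever they are defined: signed-rank up to
n = 25 with no zeros and no tied absolute differences, Mann-Whitney up
to 30 total observations with no ties. With ties the tie-corrected
normal approximation is used and the result records which route was
taken. Bonferroni adjustment is `min(1, m * p)`; the family size `m`
defaults to the number of pairwise contrasts and is carried in every
output row.

The unit of analysis defaults to the per-animal mean across that
animal's fields, avoiding pseudo-replication; a per-field mode exists
behind `unit = "field"`.

## The synthetic generator

`render_field()` draws ramified cells as a bright soma disc
(amplitude 200 of 255) with dimmer radiating process strokes
(amplitude 100) to recorded tip positions, placed by dart-throwing with
a jittered-grid fallback under a hard minimum inter-soma distance — the
mosaic. Each cell is assigned a z-plane; background and clipped Gaussian
noise are added per plane. The green channel, when configured, is a
uniform level plus noise.

Rasterization is binary-amplitude with the pixel-centre-in-shape rule
and no sub-pixel blending, so the planted pixel fraction, soma pixel
areas and punctum counts are *exactly* recoverable from the noise-free
image; this is what lets the tests assert equality rather than
approximate agreement. Process strokes are floored at a half-width of
0.72 px so they remain 8-connected at coarse rasters.

The cohort generator (`cohort_spec()`, `generate_cohort()`) expands this
to a full study: one naive group plus five lasered groups (survival
days 1, 3, 5, 8, 15), 8 animals per group, lasered animals contributing
an OHT and a contralateral eye. `default_cohort_profile()` encodes the
qualitative activation course as explicit per-group multiplier curves —
OHT plexiform counts and NFL-GCL area fraction peaking at days 3-5, OHT
soma maximal at day 1, contralateral soma maximal at day 3, vertical
processes rising monotonically in OHT eyes, P2RY12 trough at days 3-5 —
plus naive P2RY12 baselines of 18.47%, 32.21% and 14.35% of 255 for
OPL, IPL and NFL-GCL. The arbor-retraction multiplier applies only to
the plexiform layers: in the NFL-GCL, where individual arbors are not
measurable and the area fraction is the readout, the labelled area is
carried by cell accumulation and soma growth, so retraction is not
simulated there (otherwise shrinking strokes would cancel the density
rise and the rendered area-fraction course would contradict the
configured one). Between-animal variation is lognormal with
coefficients of variation of 4-6% for geometry and counts and 15% for
intensity, values typical of the spread reported for such measurements.
These curves are configuration: the generator never injects effects
beyond what the profile states, and every planted object is catalogued
in the returned `ground_truth`.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: mosaic
spacing, soma/arbor geometry with exact catalogues, dense overlapping
signal in the NFL-GCL, point-like puncta, channel intensity levels,
group/day effect curves, and per-plane noise. It does not attempt
photorealism: no branching-tree morphogenesis, no optical point-spread
function, no vessels or dendritic cells, no bleaching. Passing tests
therefore demonstrate correctness of the measurement chain and
sensitivity at realistic effect sizes — not performance on real
micrographs, where segmentation is harder than on star-shaped cells.

## Numerical choices and degenerate inputs

* All-zero fields are flagged empty and count zero cells; they never
  throw.
* Pixel (r, c) is centred at ((r−1)s, (c−1)s) for pixel size s, shared
  by renderer and measurements, so planted and measured coordinates are
  directly comparable and a 10x10 square at the origin has centroid
  (4.5, 4.5) px.
* EBImage's labeller is 4-connected; diagonally adjacent labels are
  merged afterwards to obtain the 8-connected convention.
* The green-channel "true" intensity is catalogued from the rendered
  max projection. With several noisy z-planes the projection of noise
  adds a small uniform positive offset to all groups; at a single plane
  (used in the demonstrations) the recovered percentage equals the
  configured level.
* Measured cell counts can differ slightly between groups with equal
  planted density if their arbor sizes differ, because larger arbors
  merge neighbouring components more often. Planted-null checks
  therefore use the zone analysis (zones share one parameter set by
  construction) and the contralateral P2RY12 contrast, which are free
  of this rasterization interaction.
* Arbor areas measured from skeletons run below the planted hull area
  (thinning erodes strokes inward by roughly the stroke half-width plus
  one pixel, more at coarse rasters). The bias is monotone in the
  planted arbor radius, so orderings and contrasts are preserved; tip
  *counts* are exact on noise-free rasters at fine pixel sizes.

## Problem sizes

The demonstration and validation runs use 8 animals per group, one
field per eye per layer, 192-px fields (2.0 um/px) and a single
z-plane; detection-recovery checks use 256-px fields. These sizes keep
a full cohort run under half a minute while leaving every effect of the
default profile several standard errors wide. Field count, raster size
and z-depth are ordinary configuration knobs (`cohort_spec()`), and the
same pipeline runs unchanged at finer rasters and more fields per eye.

## Known limitations

* The convex-hull arbor area cannot represent concave territory
  boundaries.
* Automated soma cores assume somata are the brightest structures;
  saturated processes would inflate soma counts.
* The exact Mann-Whitney route switches to the normal approximation in
  the presence of any tie, which for heavily discretised measurements
  (e.g. small puncta counts) makes small-sample p-values approximate.
* Fields are processed independently; no stitching or tiling of the
  meridian scans is attempted.
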