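# gliaquant

Quantification of microglial activation in retinal whole-mount
fluorescence microscopy.

Microglia tile the healthy retina as a regular mosaic of ramified cells.
After an insult such as unilateral laser-induced ocular hypertension
(OHT), they show a stereotyped activation course in both the lasered and
the untreated contralateral eye: more cells in the outer segment (OS)
and plexiform layers, enlarged somata, retracted process arbors, more
vertical processes bridging the outer plexiform layer (OPL) and the OS,
a larger Iba-1+ area fraction in the nerve fibre/ganglion cell layer
(NFL-GCL), and down-regulation of the resident-microglia marker P2RY12.
`gliaquant` implements the full measurement battery for these signs on
calibrated 20x fields of 0.1502 mm², plus a synthetic whole-mount
generator with exact ground truth and the statistical comparison scheme
used in such time-course studies. It is aimed at labs that quantify
immunolabelled whole-mounts and at anyone who needs a testable,
scriptable replacement for interactive counting tools.

## The measurements

**Cell counting (OPL, IPL).** For a max-projected field *I*:

1. normalise: *I′ = I / max(I)*, so values span [0, 1];
2. threshold: zero every value strictly below 0.2 (a value exactly at
   0.2 is kept);
3. segment: 8-connected components of the surviving mask, dropping
   components under 5 px; each contributes its unweighted centre of
   mass;
4. deduplicate: single-linkage merging of centroids at distance
   < *d*<sub>min</sub> (default 25 µm), so a cell split across segments
   is counted once.

Counts are reported per 0.1502 mm² field. The same chain with
spot-scale parameters counts the isolated OS cells (`count_spots()`)
and the vertical-process puncta in the OPL–OS interface plane
(`count_vertical_processes()`).

**Morphometry.** Iba1-RA is the thresholded pixel fraction of the field
(`area_fraction()`). Soma areas come from traced contours (shoelace
formula) or automatically from high-intensity soma cores
(`soma_areas_field()`). Arbor area is the convex hull of the cell's
skeleton-endpoint tips (`extract_tips()`, `arbor_area()`), the
deterministic counterpart of hand-drawing a polygon through the most
distal process tips.

**Intensity.** P2RY12 expression is the Image Average Intensity of the
green channel: `100 * mean(pixels) / 255` percent
(`mean_intensity_percent()`).

**Statistics.** Wilcoxon signed-rank (paired eyes of one animal),
Mann-Whitney U (vs naive animals), and one-way ANOVA with Bonferroni
correction across time points and retinal zones — exact small-sample
p-values where defined, tie-corrected approximations otherwise
(`compare_paired()`, `compare_unpaired()`, `anova_bonferroni()`,
`zone_analysis()`). The unit of analysis is the per-animal mean.

## Worked example

Simulate a cohort (8 animals per group; naive plus lasered groups at
days 1, 3, 5, 8, 15; OHT and contralateral eyes), quantify every field,
and test the contrasts:

```r
library(gliaquant)

run <- run_quantification(run_config(
  cohort = cohort_spec(n_animals = 8, fields_per_animal = 1,
                       field_px = 192, n_z = 1, master_seed = 11)))

time_course(run, "cell_count", "OPL")
#> # A tibble: 11 × 5
#>    group           day  mean    sd     n
#>    <chr>         <dbl> <dbl> <dbl> <int>
#>  1 OHT               1  20   1.31      8
#>  2 OHT               3  28.8 1.83      8
#>  3 OHT               5  32.9 2.10      8
#>  4 OHT               8  26   1.20      8
#>  5 OHT              15  21   1.51      8
#>  6 contralateral     1  16.1 0.835     8
#>  7 contralateral     3  16   1.07      8
#>  8 contralateral     5  15.8 1.04      8
#>  9 contralateral     8  16.3 0.886     8
#> 10 contralateral    15  15.9 1.13      8
#> 11 naive            NA  15.6 0.518     8
```

The OHT count in the OPL rises from ~20 cells per field at day 1 to a
peak of ~33 at day 5 and falls back toward the naive baseline (~16) by
day 15, while contralateral counts stay at baseline — the planted
course, recovered by measurement. The comparison table carries the
matching statistics (Mann-Whitney U against naive; with tied counts the
tie-corrected approximation is used and recorded):

```r
dplyr::filter(run$comparisons, metric == "cell_count", layer == "OPL",
              day == 5, contrast == "OHT vs naive")
#> # A tibble: 1 × 11
#>   metric     layer   day contrast     method       statistic    p_raw ...
#>   <chr>      <chr> <dbl> <chr>        <chr>            <dbl>    <dbl>
#> 1 cell_count OPL       5 OHT vs naive mann_whitney        64 0.000722
```

U = 64 is complete separation of the two samples of eight.

`plot_time_course(run, "cell_count", "OPL")` draws the usual
histogram-plus-dotted-naive-line figure, and `render_report(run, dir)`
writes all figures and tables at once. Single fields can be handled
directly: `render_field()`, `count_cells()`, `area_fraction()`,
`soma_areas_field()`, `extract_tips()` all work on individual images,
and `read_stack()`/`write_stack()` move calibrated TIFF z-stacks in and
out.

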