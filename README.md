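# lysoquant

Quantitative image analysis of lysosome morphology, motility and
phagosome–lysosome fusion from fluorescence microscopy.

## What this package is for

When the lipid kinase PIKfyve is inhibited, lysosomes coalesce: cells go
from many small lysosomes to fewer, larger ones at constant total
lysosomal volume. Whether a treatment (for instance, reactive oxygen
species) prevents or reverses that coalescence is decided entirely by a
panel of image-derived measurements. `lysoquant` implements that panel as
a reusable, fully tested pipeline for R:

- **3D lysosome volumetrics** from confocal z-stacks (45–55 planes at
  0.3 µm): per cell, the lysosome count *N*, individual volumes
  *V₁…V_N* (µm³, particles retained when *V* > 0.3 µm³), and the total
  volume *ΣVᵢ*. Segmentation thresholds at 2× the mean cytosolic
  intensity of the same cell, labels 26-connected components, and
  optionally splits touching aggregates by marker-based watershed on the
  anisotropic Euclidean distance transform.
- **Lysosome motility** from single-plane time-lapses (4 s or 8 s frame
  intervals): greedy nearest-neighbour linking of detected centroids, then
  per-track *track length* = Σ‖xₜ₊₁ − xₜ‖, *displacement* =
  ‖x_last − x_first‖, and *speed* = track length / (Δt · (n − 1)).
- **Microtubule morphometry**: Guo–Hall skeletonization of thresholded
  filament images, junction/branch/branch-length statistics in the style
  of the standard skeleton-analysis plugin, and watershed tubulin patch
  areas.
- **Intensity statistics**: the F_H/F_L membrane-recruitment ratio (mean
  of the 10 highest over the 10 lowest values along a 3-pixel-wide
  profile), organelle-to-cytosol ratios through a reference-channel mask,
  background-corrected per-cell probe intensities, area-gated puncta
  counts, and puncta-on-lysosome association.
- **Phagosome–lysosome fusion**: mean LAMP-1 intensity over dilated
  internal-bacteria masks built by subtraction of the external-antibody
  signal.
- **Statistics**: Student's t-test (two groups) or one-way ANOVA with
  Tukey's HSD (more), vehicle normalization, and mean ± s.e.m. summaries
  with explicit units of analysis — all returning tidy tibbles with
  broom-style `tidy()`/`glance()` methods.

No raw micrographs from the motivating study are publicly available, so
the package ships a **synthetic-microscopy scene generator**
(`generate_lysosome_stack()`, `generate_timelapse()`,
`generate_filament_image()`, `generate_phagosome_scene()`) that renders
every scene class with exact ground truth — spheres at the 0.7 µm
estimated lysosome radius, 46-frame time-lapse presets, branching filament
fields, internal/external bacteria with LAMP-1 — making every metric
testable as a parameter-recovery problem.

## Worked example

Generate a synthetic stack of 20 lysosomes (radius 0.7 µm) in one cell,
segment it, and summarise:

```r
library(lysoquant)

cfg   <- scene_config(random_seed = 1)            # 0.1 um/px, 50 planes @ 0.3 um
scene <- generate_lysosome_stack(cfg, spheres_per_cell = 20)
cell  <- scene$regions[[1]]

th   <- cytosolic_threshold(scene$image, cell)    # 2x cytosolic mean -> 99.99
segs <- segment_lysosomes(scene$image, cell, th)  # watershed split on by default
segs[1:4, 1:7]
#> # A tibble: 4 × 7
#>   label cell_id n_voxels volume_um3 centroid_x_um centroid_y_um centroid_z_um
#>   <int> <chr>      <int>      <dbl>         <dbl>         <dbl>         <dbl>
#> 1     1 cell_01      465       1.40          4.53          6.05          1.19
#> 2     2 cell_01      463       1.39          3.82          9.44          2.65
#> 3     3 cell_01      465       1.40          1.88          3.74          3.30
#> 4     4 cell_01      471       1.41         12.1           6.71          4.19

per_cell_metrics(segs)[, c("cell_id", "lysosome_count", "total_volume_um3")]
#> # A tibble: 1 × 3
#>   cell_id lysosome_count total_volume_um3
#>   <chr>            <int>            <dbl>
#> 1 cell_01             20             28.2
```

All 20 spheres are recovered; each volume sits within a few percent of the
ideal 4/3·π·0.7³ ≈ 1.44 µm³, so the per-cell total (28.2 µm³) tracks the
ground truth (20 × 1.44 = 28.7 µm³).

Group comparison in the study's reporting style (values here are
illustrative per-experiment means of individual lysosome volume):

```r
tab <- tibble::tibble(
  experiment_id = rep(c("e1", "e2", "e3"), each = 3),
  condition     = rep(c("vehicle", "apilimod", "apilimod_h2o2"), times = 3),
  value         = c(1.1, 3.4, 1.3, 0.9, 3.1, 1.2, 1.0, 3.6, 1.4)
)
compare_groups(tab)
#> One-way ANOVA (3 groups): F(2, 6) = 179.3, p = 4.455e-06
#> Tukey HSD pairs:
#>                     pair      diff  adj_p_value significant
#> 1 apilimod_h2o2-apilimod -2.066667 1.231490e-05        TRUE
#> 2       vehicle-apilimod -2.366667 5.289832e-06        TRUE
#> 3  vehicle-apilimod_h2o2 -0.300000 1.488247e-01       FALSE
```

Apilimod differs from vehicle; apilimod + H₂O₂ does not — the coalescence
read-out and its rescue, at the level of the statistics layer.

`ggplot2` helpers (`plot_condition_summary()`, `plot_tracks()`,
`autoplot()` on comparison objects) draw the corresponding dot/jitter and
pairwise-interval figures. A command-line front end covering the whole
pipeline lives in `inst/cli/lysoquant.R` (subcommands `simulate`,
`volumetrics`, `track`, `skeleton`, `phagosomes`, `report`).

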