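---
title: "Quantifying lysosome morphology, motility and fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysosome morphology, motility and fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoquant)
```

# The scientific problem

Inhibition of the lipid kinase PIKfyve (e.g. with apilimod) makes lysosomes
coalesce: cells shift from many small lysosomes to fewer, larger ones while
the total lysosomal volume stays constant. Studying what modulates this
phenotype — in particular, whether reactive oxygen species (ROS) prevent
coalescence — rests entirely on a set of image-derived measurements:

* **3D volumetrics** — per cell, the number of lysosomes, their individual
  volumes, and the total lysosomal volume, from confocal z-stacks of a
  fluid-phase dye (45–55 planes at 0.3 µm spacing).
* **Motility** — per-lysosome speed, track length, and displacement from
  single-plane time-lapses (4 s intervals for 3 min in macrophages, 8 s for
  6 min in epithelial cells).
* **Microtubule morphometry** — junctions per cell, branches per cell, and
  mean branch length of the skeletonized tubulin network, plus tubulin patch
  areas from watershed segmentation.
* **Intensity statistics** — the F~H~/F~L~ line-profile ratio for membrane
  recruitment, organelle-to-cytosol ratios through a reference mask,
  background-corrected whole-cell probe intensities, area-gated puncta
  counts, and actin-puncta-on-lysosome association.
* **Phagosome–lysosome fusion** — mean LAMP-1 intensity on
  internal-bacteria phagosome masks.
* **Statistics** — Student's t-test for two groups, one-way ANOVA with
  Tukey's post-hoc test for more, vehicle normalization, mean ± s.e.m.
  reporting.

`lysoquant` reimplements this entire quantification layer as composable,
tested functions. Because no raw micrographs are publicly deposited, the
package pairs every analysis with a **synthetic scene generator** that
renders the same classes of images with exact, machine-readable ground
truth. Every claim the test-suite makes is a *parameter-recovery* claim:
the pipeline, run on scenes whose true geometry is known, must return that
geometry.

# The image model

All generators share one forward model:

1. **Geometry** is defined in continuous micrometre coordinates. A voxel is
   part of an object when its *centre* lies inside the object; the centre
   of voxel `(i, j, k)` (1-based) is at `((i − 0.5)·Δ, …)`. This half-pixel
   convention removes ambiguity from every recovery test.
2. **Optics** are approximated by a Gaussian blur of physical width
   `psf_sigma` (default 0.1 µm, a plausible lateral sigma for a 63×/1.4 NA
   system), applied separably per axis so the blur is anisotropic in voxel
   units (the 0.3 µm z-step).
3. **Background** of `background_level` (default 50) is added inside cell
   footprints — the cytosolic dye level that anchors thresholding.
4. **Noise** is additive Gaussian (`gaussian_sd`, default 5) with optional
   Poisson resampling (`poisson_scaling`).

With `psf_sigma = 0` and no noise, the above-background voxels equal the
rasterized geometry exactly — a conservation invariant that is tested.

A deliberate calibration: the default sphere intensity is **twice the
background**. The segmentation threshold is twice the cytosolic mean, so it
falls exactly at the *half-maximum* of a blurred object boundary — the
condition under which global thresholding recovers an object's geometric
size. With much brighter objects the same rule would cut far down the blur
skirt and systematically inflate volumes; that regime can be explored by
setting `intensity` explicitly.

What the generator does **not** emulate: vectorial/depth-varying PSFs,
spectral bleed-through, photobleaching, or cell-shape dynamics (the
wobbling of rounded macrophages). Passing recovery tests therefore
demonstrates the correctness of the measurement code under a simplified
but standard confocal model, not robustness to every artefact of real
data.

# Volumetrics

`cytosolic_threshold()` returns `factor × mean(cytosol sample)` (default
factor 2). The comparison is strict (`voxel > threshold`), so a uniform
image deterministically yields zero segments. Segmentation uses
26-connectivity (8 in 2D), the permissive standard; the particle gate is
*strictly greater than* 0.3 µm³, a literal reading of the inclusion rule.

`watershed_split()` separates touching organelles: seeds are local maxima
of the anisotropy-corrected Euclidean distance transform (axes scaled by
voxel size before distances), plateaus collapse to one representative, and
seeds closer than `min_volume^(1/3)` are greedily thinned, strongest
first. Flooding proceeds from deep to shallow with a priority queue.

Two numerical choices deserve a note:

* **Plateau flooding is breadth-first.** Quantized distance maps contain
  large equal-distance shells. If ties were broken globally by seed label,
  the lowest label would annex whole plateaus, producing grossly
  asymmetric splits of symmetric pairs. Equal-priority queue entries are
  therefore processed first-in-first-out, which advances all fronts one
  shell at a time; seeds are enqueued in label order, so genuinely
  simultaneous claims still resolve to the lower label. On analytic
  two-sphere fixtures this reproduces the nearest-centre partition
  exactly, which is the behaviour the splitting step exists to deliver.
* **Voxel conservation is exact**: the union of output regions equals the
  input component; this is asserted on every fixture.

The commercial tool originally used for volumetrics does not document its
watershed algorithm; only conservation and truth-recovery are promised
here, not voxel-level equivalence with that tool.

# Motility

Detection thresholds a frame (same 2×-cytosol doctrine, with the dimmer
half of the frame standing in for the cytosol when no region is supplied),
labels 8-connected components and takes intensity-weighted centroids.
Linking is deliberately the simplest deterministic scheme: candidate pairs
between consecutive frames in ascending distance order, a hard gate of
`max_step` (default 2 µm/frame, generous against observed lysosome
speeds), no gap closing, no merge/split. The commercial tracker's settings
are unreported, so population-level comparisons with published motility
values are out of reach by construction; only synthetic recovery is
claimed. Tracks shorter than 3 points are excluded from summaries (speed
of 2-point tracks is noise-dominated); the exclusion count is reported.

Metrics per track: `track_length = Σ` consecutive Euclidean steps,
`displacement` = first-to-last distance, `speed = track_length /
(frame_interval · (n − 1))`. Displacement can never exceed track length;
this is property-tested on 1,000 simulated random walks.

In the generator, particles reflect off the field boundary *with velocity
reversal* — folding the position alone would trap constant-velocity
particles rattling at a wall with near-zero net step, corrupting the
ground truth that recovery is judged against.

# Skeleton morphometry

Filament images are converted to 8-bit before thresholding (Otsu on
in-cell pixels by default, fixed values accepted). Thinning uses the
Guo–Hall two-subiteration algorithm followed by removal of redundant
corner pixels (pixels whose 8-neighbourhood forms a single contiguous
arc). Guo–Hall was chosen over Zhang–Suen because the latter leaves
staircase artefacts on oblique lines; those artefacts masquerade as
junction pixels and, on randomly oriented filament fields, inflated
junction counts several-fold before the switch.

Skeleton pixels are classified by 8-neighbour count: 1 = endpoint, 2 =
slab, ≥3 = junction candidate. Adjacent candidates merge into one junction
node — a thick crossing thins into a small cluster of candidate pixels,
but it is one biological junction. Branches are maximal slab paths;
lengths accumulate 1 px per orthogonal and √2 px per diagonal step (the
convention of the standard skeleton-analysis plugin), including the step
onto an adjacent junction cluster. Spurs shorter than 3 px ending at a
free endpoint are pruned (thinning artefacts; threshold exposed). A slab
bridge of fewer than 3 px connecting two junction clusters is treated as
part of a single junction: dense multi-way crossings thin into two nearby
clusters joined by such a bridge.

Patch analysis watersheds the binary mask (2D variant of the same
distance-transform seeding) and reports the **maximum** patch area per
cell as the headline (the mean is also emitted, since the published
description is ambiguous between the two).

These measures are proxies of network structure, not absolute descriptors;
no attempt is made to reproduce published magnitudes, only the defined
computations.

# Intensity metrics

* **F~H~/F~L~**: profile values of a 3-pixel-wide, 20–40-pixel line are
  width-averaged, sorted, and the mean of the top 10 divided by the mean
  of the bottom 10. Means rather than sums are used; for equal counts the
  ratio is identical either way. The ratio is ≥ 1 by construction,
  invariant under positive scaling, and a profile whose lowest decile
  reaches zero is rejected rather than clamped. Line placement mirrors the
  blinded-grid intent deterministically: a fixed 4×4 anchor grid per cell
  bounding box, nucleus-overlapping lines discarded, seeded selection.
* **Organelle-to-cytosol ratio**: the reference channel (dextran, etc.) is
  thresholded by the same 2×-cytosol rule into a mask; the ratio is
  (marker mean over mask − background) / (marker mean over cytosol
  excluding mask − background). An empty reference mask yields a flagged
  `NA`, never a silent zero.
* **Puncta counting** gates 8-connected components by area. The default
  gate is 50–1000 µm² exactly as published; that unit is implausibly large
  for galectin puncta and is likely pixel² in the original, so the gate
  value and unit are both configurable (`gate_unit = "px"`), flagged
  rather than silently corrected.
* **Association** of a punctum with lysosomes means its centroid lies
  within `association_distance` (default 0.25 µm ≈ 2–3 px; no published
  criterion exists) of the lysosome mask, measured by distance transform.

# Phagosome–lysosome fusion

Internal bacteria are isolated by subtraction masking: any all-bacteria
component overlapping the external-antibody mask by one pixel is external
in toto (the antibody decorates whole bacteria). Components of ≤ 4 px
(configurable) are removed as noise, mirroring the manual cleanup of "a
few pixels". The mask is dilated by a Euclidean disk (default 3 px —
"dilated to reach the phagosome edge" is unquantified, so the radius is
exposed and the CLI reports a 1–6 px sensitivity sweep), external pixels
are carved out after dilation, and the score is the background-corrected
LAMP-1 mean over each cell's mask union (headline) alongside the mean of
per-phagosome means, since the published description is ambiguous between
the two.

One generator design choice matters here. A LAMP-1 *annulus* around a dark
bacterium cannot be recovered by a superset mask: the mask necessarily
includes the dark core, diluting the mean to roughly the ring's area
fraction. At confocal resolution, however, a 0.3–0.4 µm membrane shell
around a 0.5 µm-radius bacterium is not resolved and appears filled, so
the generator's default renders LAMP-1 filled out to the membrane
(`lamp_filled = TRUE`); the bare annulus remains available for tests of
ring coverage. With the filled rendering, the noiseless fixture recovers
the stated ring intensity exactly, and half-intensity "reduced fusion"
scenes score below controls in every seeded replicate — the metric-level
analogue of the biological readout.

# Statistics

Two groups: two-tailed unpaired Student's t-test (equal variances — the
classical form). Three or more: one-way ANOVA with Tukey HSD on all pairs,
using the Tukey–Kramer standard error for unequal group sizes. The
published methods text prints "significance was defined as *P*>0.05",
an evident typo given that every figure legend marks significance at
p<0.05; the package implements p < 0.05 and records the discrepancy here
rather than silently.

The unit of analysis deserves care: figures plot per-cell dots, but cells
within an experiment are not independent. `summarize_conditions()`
defaults to experiment means (avoiding pseudo-replication) with a per-cell
option, and always reports both sample sizes. `normalize_to_vehicle()`
divides by the vehicle mean per experiment, making the control mean
exactly 1.

ANOVA, Tukey and the t-test are delegated to R's `aov()`, `TukeyHSD()` and
`t.test()`; the test-suite verifies them against hand-coded
sum-of-squares/studentized-range formulas to six decimals, and checks the
F = t² identity on two-group fixtures.

# Problem sizes and determinism

The default test-suite scenes are one 15 × 15 µm cell with 20 spheres over
50 z-planes (≈ 1.1 M voxels), 46-frame time-lapses, 300 × 300 px filament
and phagosome fields, and 10–50 seeded replicates per property —
sizes chosen so each scene is generated and analyzed in under a few
seconds while leaving every geometric feature (sphere separation, junction
spacing ≥ 10 px, ring widths of a few pixels) comfortably resolved.
Identical `scene_config`s (including the seed) reproduce scenes
bit-for-bit; all stochastic tests fix their seeds.

# Known limitations

* Sphere placement uses rejection sampling with a centre-distance floor of
  `0.5·(r₁+r₂)` (default 1.3× the radius sum); extremely crowded requests
  fail with an explicit error rather than degrading.
* The tracker has no gap closing: a single missed detection splits a
  track. This is by design (determinism first) and documented, not hidden.
* Skeleton topology recovery is exact only for networks whose junctions
  are separated by ≳ 10 px at the rendered widths (2–4 px); dense 8-way
  crossings can still thin into two merged-by-bridge clusters counted as
  one junction but, at extreme densities, may not.
* The watershed promises conservation and truth recovery, not equivalence
  with any particular commercial implementation.
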