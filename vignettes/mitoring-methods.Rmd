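---
title: "Methods: ring-resolved mitochondrial polarization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ring-resolved mitochondrial polarization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoring)
```

## The measurement model

`mitoring` quantifies a potential-dependent mitochondrial dye
(MitoTracker CMX ROS, the *potential* channel) relative to a
potential-independent mass marker (Tom70 immunofluorescence, the
*marker* channel) inside the mitochondrial compartment that the marker
demarcates, with nuclei from a DAPI channel. Three readouts are computed
for any region of interest, from intensity sums `M` (potential), `T`
(marker) and the mitochondrial area `A` in µm²:

* `ratio_potential_marker = M / T` — the membrane-potential proxy,
  insensitive to mitochondrial abundance;
* `potential_per_area = M / A` and `marker_per_area = T / A` — dye and
  marker density per unit compartment area.

The underlying assumptions are the standard ones of ratiometric
immunofluorescence: a scalar additive background per image, intensities
proportional to epitope/dye amount within the linear range of the
detector, and a marker channel whose threshold separates compartment
from background. Spatial heterogeneity is resolved by concentric rings of
fixed width around each nucleus; ring 1 is perinuclear and profiles are
normalized to it, which removes per-cell scale and isolates the radial
*shape* of the profile.

## Ring construction and the distance convention

Rings are built from an exact Euclidean distance transform of the
nucleus complement. A pixel's distance is its distance to the nearest
nucleus pixel **minus half a pixel**, clipped at zero — i.e. distance 0
sits at the nucleus pixel edge, not at its centre. Ring `k` is the
half-open band `[(k−1)·w, k·w)` (default `w` = 1 µm, 4 rings), so rings
are disjoint by construction, ring 1 touches the nucleus, and a pixel at
exactly one ring width falls in ring 2.

The half-pixel correction matters: raw centre-to-centre distances are
bounded below by one pixel and overestimate the boundary distance by
about 0.75 px on average, which systematically starves the innermost
ring. With the correction, ring areas around a disc nucleus converge to
the continuum annulus areas as the pixel size shrinks (all four 1-µm
rings around a 10-µm disc are within ~3 % of π((r+k)² − (r+k−1)²) at
0.125 µm/px, and within ~9 % at 0.25 µm/px). At coarse resolution the
approximation degrades for a discrete-geometry reason worth knowing
about: when the ring width approaches one pixel, the available distance
values (1, √2, 2, √5, … pixels) are too sparse to partition pixels into
annuli of the continuum areas, and *no* threshold convention can reach
them — ring areas at 1 µm/px with 1-µm rings are off by up to ~30 %.
Analyses should therefore use pixel sizes of at most about a quarter of
the ring width; typical confocal pixel sizes (0.1–0.25 µm) are fine.

By default rings are clipped to the cell's territory (every pixel is
assigned to the nucleus with the nearest boundary, ties to the lower
label), so rings of neighbouring cells never overlap in crowded fields.
Rings are *not* clipped to the mitochondrial mask; the metrics intersect
with it explicitly.

## Aggregation, normalization and QC

Region metrics use ratios of sums (`ratio_mode = "sum"`), not means of
per-pixel ratios: summing first weights pixels by their marker content
and avoids amplifying noise at dim pixels, and it makes metrics additive
over disjoint regions (sums add; ratios recompute from the summed
numerator and denominator). The per-pixel mean is available as
`ratio_mode = "pixel_mean"` for sensitivity analyses.

Cells whose ring-1 value is missing or zero cannot be normalized; they
are excluded from profiles and counted in a QC record rather than
failing the run, so that excluded + analyzed always equals segmented.
Group-level normalization (`normalize_to_control()`) divides by the
control's mean within each experiment, mapping the control to exactly
1.0; a missing or zero control is an error naming the experiment.

## Segmentation choices

* **Background**: one scalar per image. The default estimator is the
  histogram mode (exact tabulation when there are few distinct values,
  otherwise the densest of 256 bins), because the mode of a
  noise-broadened background plateau is unbiased under symmetric noise,
  whereas a low percentile (the selectable alternative, default level
  1 %) underestimates the background by roughly 2.3 standard deviations
  of the noise and leaves a residual offset that biases ratio metrics.
* **Nuclei**: global Otsu threshold, hole filling, minimum area
  (default 20 µm²) to reject debris. An empty result is a warning, not
  an error.
* **Mitochondria**: Otsu on the background-corrected marker channel,
  per cell territory by default (robust to cell-to-cell staining
  differences), excluding nucleus pixels, with a minimum object area of
  0.1 µm² to remove single-pixel noise. Thresholding after rescaling by
  the image maximum makes segmentation invariant to multiplying a
  channel by a positive constant.
* **Border cells**: cells whose nucleus lies within 4 µm (the default
  ring extent) of the field edge are flagged, and optionally excluded,
  because their outer rings are truncated.

Coordinates follow R's 1-based matrix convention; areas are reported in
both pixels and µm² (µm² = px · pixel_size²).

## Morphology

Fragmentation is quantified per cell from connected components of the
mitochondrial mask: object count, mean/median object area, total area,
mean major-axis length, and the fragmentation index = objects per µm².
The default connectivity is 8 (thin, obliquely oriented organelle
profiles frequently touch diagonally); 4-connectivity is available and
the choice is recorded in the output. The 8-connected count never
exceeds the 4-connected count, and splitting a fixed-area network into
n pieces multiplies the index by n.

## Statistics

Group summaries report mean and SEM (sample SD with the n−1 denominator
over √n; a single value reports SEM as missing rather than zero).
Two-group comparisons use the two-tailed Student t-test (pooled variance
by default, matching the classical test; Welch optional). Multi-group
comparisons use one-way ANOVA followed by pairwise t-tests with
Bonferroni adjustment `p_adj = min(1, p · m)`. The family size `m` is an
explicit, required choice with no silent default because it differs
between designs: `m = g − 1` when comparing every group against a
reference (e.g. rings 2–4 vs ring 1), `m = g(g−1)/2` for all pairs.
α is 0.05 and configurable. Degenerate inputs are handled without
failure: identical groups give t = 0, p = 1; two identical groups give
F = 0, p = 1.

## The synthetic generator

The generator emulates the statistical structure that the analysis
assumes, with ground truth for every stage:

* elliptical, non-overlapping nuclei (semi-axes drawn from
  `nucleus_radii_um`, default 4–6 µm, random orientation; ≥ 2 µm apart);
* mitochondria as random-walk polylines seeded near the nucleus with
  outward drift, dilated to `mito_width_um` (default 0.5 µm), mean
  curvilinear length `mito_object_length_um` (default 3 µm), giving a
  perinuclear-dense network; a minimum inter-object gap (default
  0.4 µm) is enforced so programmed object counts stay recoverable, and
  crowded perinuclear shells spill outward rather than failing;
* linear radial intensity laws on mitochondrial pixels at boundary
  distance `d` from the owning nucleus (same distance convention as the
  analysis): `marker = marker_density · (1 + marker_slope · d)` and
  `potential = marker · polarization_base · (1 + polarization_slope · d)`
  — defaults 100 a.u., slope −0.04/µm, base 1.5, slope +0.08/µm, i.e. a
  mass density that falls and a potential-per-marker ratio that rises
  towards the periphery;
* camera noise: Poisson on the signal (`poisson_scaling` = 2 counts per
  a.u.) plus additive Gaussian (`gaussian_noise_sd` = 8 a.u.) on a
  background of 20 a.u., clipped at zero — roughly SNR 10 at the default
  marker level. All noise is seeded; equal parameters give bit-identical
  scenes and renders.

Four presets encode qualitative treatment archetypes (`vehicle`,
`hyperpolarized_fragmented` with a 1.3× potential baseline and more,
shorter objects, `marker_up_gradient_steep`, `gradient_flattened`).
Their magnitudes are free design parameters of the simulator chosen once
for direction, not fits to any measured data.

What the generator does **not** emulate: point-spread-function blur and
out-of-focus light, photobleaching and stage drift, intensity
vignetting, partial-volume effects at object boundaries (objects are
binary at pixel resolution), 3D structure, and mitochondrial dynamics.
Passing the validation suite therefore demonstrates correctness of the
measurement pipeline under the stated image-formation model, not
robustness to every confound of real microscopy — in particular,
segmentation accuracy on real data depends on optics and staining
quality in ways the synthetic scenes cannot probe.

## Validation problem sizes

The test suite validates: ring assignment against an exhaustive
nearest-pixel scan on random 128×128 nucleus masks; noiseless
end-to-end recovery of programmed ring profiles within 1 % and exact
object counts; noisy (SNR ≈ 10) recovery of the normalized ring-4 value
within 5 % over 50 single-cell fields, of programmed whole-cell ratio
effects (1.1×, 1.25×, 1.5×) within 3 points at 50 cells per group, and
of object counts within 10 %; t-test type-I error within [0.035, 0.065]
over 1000 null replicates of two n = 35 groups; and bitwise
reproducibility of a full run from its saved YAML config. Single-cell
fields of 160×160 px at 0.25 µm/px keep these checks fast while leaving
room for four 1-µm rings around a 4–6 µm nucleus.

## Known limitations

* 2D only; a single optical section (or a pre-computed projection) is
  assumed.
* Ring areas — and with them per-area metrics of the innermost ring —
  are biased when the pixel size exceeds about a quarter of the ring
  width (see the distance-convention section).
* Per-cell Otsu assumes each territory actually contains mitochondrial
  signal; fields with empty cells should use the global method or a
  minimum-area filter.
* Territory assignment is Euclidean, not geodesic: in highly concave
  cell arrangements a pixel can be assigned across a neighbouring
  cell's process.
* The marker is treated as potential-independent; if a treatment alters
  marker binding itself, the ratio conflates the two effects — the
  per-area readouts help disentangle them.
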