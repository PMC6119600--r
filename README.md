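# mitoring

Ring-resolved quantification of mitochondrial polarization and spatial
heterogeneity in multi-channel fluorescence micrographs.

## The problem

The mitochondrial membrane potential (Δψ_m) drives ATP synthesis and
protein import, and it is not uniform within a cell: mitochondria near the
nucleus and at the cell periphery can differ systematically. A standard
way to measure this with fixed-cell imaging is ratiometric: a
potential-dependent dye (MitoTracker CMX ROS) is quantified relative to a
potential-independent mitochondrial mass marker (Tom70
immunofluorescence), inside the mitochondrial compartment that the marker
itself demarcates. Spatial heterogeneity is resolved by concentric,
non-overlapping rings of fixed width (1 µm by default) drawn around the
DAPI-stained nucleus: ring 1 is perinuclear, higher rings are progressively
peripheral.

`mitoring` implements this workflow end to end for 2D micrographs, for
cell biologists who want per-cell and per-ring readouts with reproducible
statistics:

1. **Preprocessing and segmentation** — scalar background subtraction per
   image (histogram mode or low percentile); Otsu segmentation of nuclei;
   partition of the field into cell territories by nearest-nucleus
   distance; Otsu demarcation (global or per cell) of the mitochondrial
   compartment from the marker channel.
2. **Ring ROIs** — an exact Euclidean distance transform of the nucleus
   complement (distance 0 at the nucleus pixel edge) binned into half-open
   intervals `[(k−1)·w, k·w)` gives disjoint rings; rings are clipped to
   the cell's territory so neighbouring cells never share pixels.
3. **Readouts** per (cell × region), with `M` the summed MitoTracker
   intensity, `T` the summed Tom70 intensity and `A` the mitochondrial
   area (µm²) inside the region:
   * `ratio_potential_marker` = M / T (the Δψ_m proxy),
   * `potential_per_area` = M / A,
   * `marker_per_area` = T / A (mitochondrial mass density).
   Ring profiles are normalized to ring 1; group comparisons are
   normalized to a vehicle control.
4. **Fragmentation morphometrics** — connected components (4/8
   connectivity) of the mitochondrial mask per cell; the fragmentation
   index is objects per µm² of mitochondrial area.
5. **Statistics** — mean ± SEM summaries, two-tailed Student/Welch
   t-tests, one-way ANOVA with Bonferroni-corrected pairwise tests
   (vs-reference or all-pairs families), α = 0.05.
6. **Synthetic scenes** — a generator that places elliptical nuclei and
   curvilinear mitochondria with programmed radial intensity laws
   (`potential/marker = b·(1 + s·d)` at distance `d` from the nucleus)
   plus Poisson/Gaussian camera noise, with per-pixel ground truth, so
   every stage above can be validated without real data.

## Worked example

```r
library(mitoring)

params <- scenario_preset("vehicle", seed = 7,
                          field_size_px = c(160, 160), pixel_size_um = 0.25)
scene  <- generate_scene(params)   # ground truth: masks + programmed ratios
img    <- render(scene)            # 3-channel image with camera noise
q      <- quantify_image(img, run_config(seed = 7))

q$cells[, c("mito_area_um2", "ratio_potential_marker",
            "potential_per_area", "marker_per_area")]
#>   mito_area_um2 ratio_potential_marker potential_per_area marker_per_area
#> 1         56.75               1.933093           2628.571        1359.775

ring_profile_summary(ring_profile(q$rings, "ratio_potential_marker"))
#>   ring mean_normalized sem n
#> 1    1        1.000000  NA 1
#> 2    2        1.042944  NA 1
#> 3    3        1.121865  NA 1
#> 4    4        1.186056  NA 1

q$morphology[, c("object_count", "total_area_um2", "fragmentation_index")]
#>   object_count total_area_um2 fragmentation_index
#> 1           40          56.75           0.7048458
```

The estimated whole-cell MitoTracker/Tom70 ratio (1.93) and the rising
ring profile (ring 4 ≈ 1.19 × ring 1) recover the programmed ground truth
of this scene (`scene$truth_table`: ring-1 ratio 1.589, ring-4 ratio
1.916, i.e. a true normalized ring-4 value of 1.206) from a render at
SNR ≈ 10; all 40 programmed objects are found. `run_experiment()` runs
multi-condition studies from a YAML-serializable `run_config()` and
writes per-cell, per-ring, morphology and comparison CSVs plus QC and
provenance records; a thin command-line wrapper lives in
`inst/scripts/mitoring.R` (`simulate`, `quantify`, `run`).

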