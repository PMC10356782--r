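# mxif3d

3D reconstruction and spatial analysis of multiplexed immunofluorescence
(MxIF) serial sections.

A 5 µm tissue section is a nearly 2D sample of a 3D organ: distances
measured in-plane to structures that continue above or below the section
(blood vessels, the skin surface) systematically overestimate the true 3D
distances, and nuclei spanning several sections are double-counted.
`mxif3d` rebuilds a serial-section MxIF stack into a physically scaled
volume and analyses cell spatial organisation in it. It is aimed at
image-analysis scientists working with multiplexed serial sections (skin
in the shipped examples, but nothing is skin-specific except the surface
metric).

The pipeline:

1. **Preprocess** — illumination correction
   (`(I − background·exposure_ratio) / flatfield`), per-slide zero-mean
   unit-variance normalisation, and an autofluorescence (AF) tissue mask
   (Otsu + morphological closing + largest component).
2. **Segment & classify** — nuclei by multiscale Laplacian-of-Gaussian
   detection with watershed splitting; per-marker probabilistic
   classification by a two-component Gaussian mixture over pixel
   intensities (positive class = higher-mean component); nucleus-level
   calls requiring both mean probability ≥ 0.5 and ≥ 10% of nucleus pixels
   above threshold; phenotypes by marker logic (CD31+ endothelial;
   CD3+CD4+FOXP3+ Treg; CD3+CD4+ T helper; CD3+CD8+ T killer; CD68+
   macrophage; AE1/CK26+ epithelial).
3. **Register** — every section's masked AF image to a reference section:
   block-matching affine (patch-wise normalized cross correlation, trimmed
   least squares) followed by B-spline deformable refinement guarded by
   normalized mutual information. QC: Dice coefficient
   `DSC = 2|A∩B|/(|A|+|B|)` of registered masks vs the reference, and NCC
   between adjacent registered AF sections. Optional 3D affine refinement
   against an external reference volume counters cumulative drift.
4. **Reconstruct** — stack sections at `z = physical_index × 5 µm`
   (skipped sections leave true gaps) and fuse overlapping nuclei across
   adjacent sections into 3D cells by 26-connected components.
5. **Spatial analytics** — per-cell 2D (same-section) and 3D distances to
   the nearest vessel voxel with the exact axis-pruning search, distances
   of p53/Ki67/DDB2+ cells to the skin surface, T-cell cluster density
   within 15 and 30 µm, cell densities per cm³, and KS / Spearman+BH /
   Wilcoxon statistics.

A synthetic-phantom generator with complete ground truth (cells, vessels,
surface, per-section warps) makes every stage testable without any
external data.

## Worked example

```r
library(mxif3d)

cfg <- pipeline_config(
  phantom = phantom_config(n_sections = 6, seed = 5,
    cell_density_per_type = c(Thelper = 40, Tkiller = 6, Treg = 8,
                              macrophage = 12, endothelial = 12,
                              epithelial = 25, other = 10)),
  seed = 5)
report <- run_pipeline(cfg)
report
#> <mx_run_report>
#> # A tibble: 7 × 3
#>   stage       status seconds
#>   <chr>       <chr>    <dbl>
#> 1 input       ok      5.45
#> 2 preprocess  ok      0.0929
#> 3 register    ok     30.2
#> 4 resample    ok      3.68
#> 5 segment     ok      7.37
#> 6 reconstruct ok      0.296
#> 7 spatial     ok      0.160
#>   2D cells 116, 3D cells 103; mean DSC 0.989; mean adj NCC 0.753

glance(report)
#>   n_sections n_cells_2d n_cells_3d mean_dsc mean_adjacent_ncc mean_d2d_um mean_d3d_um
#> 1          6        116        103    0.989             0.753        46.8        25.5

report$stats
#>   test          statistic  p_value
#>   ks_two_sample     0.444  4.66e-05
```

Reading the numbers: 116 per-section nuclei fuse into 103 distinct 3D
cells (nuclei spanning two sections are no longer double-counted); the
mean immune-cell-to-vessel distance drops from 46.8 µm measured in-plane
to 25.5 µm measured in 3D — vessels run obliquely, so the nearest vessel
voxel is usually in a neighbouring section — and the KS test confirms the
2D and 3D distance distributions differ (D = 0.44). Registration QC: mean
mask Dice 0.989 against the reference section, mean adjacent-section AF
correlation 0.753.

Individual stages are ordinary functions on matrices and tibbles:

```r
sim  <- simulate_marker_section(n_cells = 500, positive_fraction = 0.4,
                                snr = 6, seed = 7)
nuc  <- segment_nuclei(normalize_zmuv(sim$section$channels$DAPI))
fit  <- fit_gmm_two_class(normalize_zmuv(sim$section$channels$CD68), seed = 7)
tidy(fit)                      # component means / sds / weights
calls <- call_marker_on_nuclei(fit, nuc, marker = "CD68")
classification_metrics(calls, nuc, sim$truth)
```

Plots: `autoplot(registration)` for per-section QC,
`plot_distance_comparison(report$distances)` and
`plot_cluster_density(report$clusters)` for the spatial results. A thin
CLI (`inst/scripts/mxif3d-cli.R`) exposes `phantom`, `register` and `run`
subcommands for shell use.

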