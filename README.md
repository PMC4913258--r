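# lipidquant

Quantifies intracellular lipid droplets in single cells from calibrated
photon-counting microscopy z-stacks, as produced by label-free coherent
Raman (CARS) imaging of hepatocyte-like (HepaRG) cells, and compares
droplet populations across treatment conditions such as HDAC-inhibitor
(Entinostat) exposure and oleate overload.

Lipid droplets appear as bright, near-spherical objects on a dark
cytoplasmic background. For each segmented cell the package measures

- the droplet count (2D watershed analysis on the brightest z-section),
- droplet radii `r = sqrt(A/pi)` and their size classes — *budding*
  (r < 0.2 um), *growing* (0.2 <= r <= 0.8 um), *large* (r > 0.8 um),
- total lipid volume (3D 26-connected components, voxel volume
  0.098^2 x 0.3 um^3),
- droplet centroid distance to the nucleus edge,

and then summarises populations (median, half interquartile range,
box/whisker statistics with whiskers at mean +- 1 sd) and tests all
treatment pairs with two-sided Wilcoxon rank-sum tests (mid-ranks,
exact enumeration for small samples, tie-corrected normal approximation
otherwise). Comparative-Ct qPCR fold inductions
(`2^-(Cp_target - Cp_18S)`, treated over untreated ratio of replicate
means) complete the gene-expression side of such experiments.

The measurement chain is: dead-time saturation correction
`n = n_obs/(1 - n_obs tau/T)` for the photon-counting detector →
Anscombe + a-trous wavelet denoising → laser-power normalisation →
per-cell splitting → thresholding at three documented operating points
(sensitive Poisson-quantile counting threshold, PSF-derived
droplet-boundary sizing threshold, field-pooled Otsu volume threshold)
→ watershed separation of touching droplets → morphometry → statistics.

Because raw stacks for such experiments are generally not deposited,
the package includes a first-class synthetic-data generator:
`make_preset()` provides four treatment presets calibrated to the
reference population medians (7/121/96/199 droplets per cell;
large-droplet fractions 2.7/2.7/7.9/13.3%; median volumes up to
536 um^3), and `render_stack()` produces calibrated noisy stacks with
exact ground truth (droplet centres and radii, cell and nucleus masks)
so the whole pipeline can be validated end to end. See the methods
vignette (`vignettes/droplet-quantification-methods.Rmd`) for the
model, parameter rationale and known limitations.

## Worked example

Simulate two treatment conditions, run the full analysis, and compare
the populations:

```r
library(lipidquant)

out <- run_pipeline(run_config(
  presets = c("control", "entinostat"),
  n_cells = 12, seed = 1
))

out$stats$per_treatment
#>    treatment n_cells count_median count_p25 count_p75 volume_median_um3
#> 1    control      12         10.5       6.0     12.75             3.347
#> 2 entinostat      12        122.0     113.8    147.50           113.132

out$stats$pairwise_counts[, c("group1", "group2", "p_value", "reject")]
#>    group1     group2      p_value reject
#> 1 control entinostat 3.587626e-05   TRUE
```

The drug-treated cells carry an order of magnitude more droplets
(median 122 vs 10.5, near the calibrated 121 vs 7) and ~30x the lipid
volume (113 vs 3.3 um^3); the rank-sum test rejects equality of the
two count distributions far below the 1% level.
Per-droplet records live in `out$droplets` (one row per droplet:
radius, size class, nucleus distance), per-cell aggregates in
`out$cells`, and `plot_cell_box()`, `plot_radius_histogram()` and
`plot_distance_scatter()` reproduce the standard views of these data.

Ground truth for every simulated run is returned alongside
(`out$truth_droplets`), so recovered and true populations can be
joined by `cell_id` — the package's own acceptance checks do exactly
that.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/lipidpipe.R run-all --presets control,entinostat \
    --cells 12 --seed 1 --out results/
Rscript inst/cli/lipidpipe.R simulate --preset combined --cells 4 \
    --seed 7 --out sim/
```

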