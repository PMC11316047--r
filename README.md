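# mitoquant

Quantitative mitochondrial phenotyping from multi-channel fluorescence
microscopy, for cell biologists studying mitochondrial quality control:
morphology (3D segmentation and principal-axis morphometry), mitophagy
readouts (autophagosome puncta, Parkin recruitment, acid-quenched dual
reporters, cargo-selective mitochondria-derived vesicles), live-cell motility
(vesselness segmentation, skeleton branch graphs, assignment tracking), and
the statistics used to compare conditions. A synthetic-microscopy generator
with exact ground truth makes every stage verifiable without external data.

## The quantities at the core

* **Elongation** of a segmented 3D mitochondrion: `E = a1 / ((a2 + a3) / 2)`,
  where `a_i = 2 * sqrt(5 * lambda_i)` are the principal axis lengths from the
  eigenvalues of the voxel-coordinate covariance (the uniform-ellipsoid
  convention); `E = 1` for a sphere. Size classes by volume: MDV-sized
  (< 0.03 um^3), network (> 1 um^3), intermediate.
* **Puncta assays** on maximum projections: rolling-ball background
  subtraction, intensity threshold, strict > 0.01 um^2 area filter. A
  mitolysosome ("mCherry-only") call requires a line-profile ratio
  `rho = (peak - bg) / bg >= 2` on mCherry together with absent GFP
  (`rho < 0.5`). FWHM of a Gaussian spot profile is `2 * sqrt(2 * ln 2) * sigma`.
* **Dynamics**: histogram-matching bleach correction; multiscale Frangi
  vesselness with a Frobenius-norm gate; semantic threshold `1e-5` on the
  normalised response; connected-component instances; medial-axis skeleton
  branch graphs; frame-to-frame Hungarian assignment with cost
  `d/(v_max dt) + |dV|/(V_i+V_j) + |da1|/(a1_i+a1_j)` and a speed gate.
* **Statistics**: ROUT outlier removal (median/RSDR with an FDR screen at
  Q = 0.01), Shapiro-Wilk normality gating into t test / ANOVA (+ Dunnett or
  Tukey) versus Mann-Whitney / Kruskal-Wallis (+ Dunn, Holm-adjusted), and
  per-replicate normalisation to the control mean.

## Worked example

Simulate a knockout-like cell, segment its mitochondria in 3D, and summarise:

```r
library(mitoquant)

cfg   <- scene_preset("morpho", "ko", seed = 1)
scene <- generate_scene(cfg)
scene$volume
#> ImageVolume: 128 x 128 x 10 [y,x,z]
#>   channels: tom20, pdh
#>   voxel size (um): x=0.1 y=0.1 z=0.3

res <- assay_morpho(scene$volume, threshold = 150)
res$cell
#>   cell n_objects median_elongation total_volume_um3 n_network n_intermediate n_mdv_sized
#> 1    1        11                 8            1.566         0             10           1
```

The cell contains 11 segmented objects with a median elongation of 8 (long
tubular mitochondria; a sphere would score 1), 1.57 um^3 of total
mitochondrial volume, and one MDV-sized object (< 0.03 um^3).

Recover an encoded effect size through the full LC3 counting pipeline
(projection, background subtraction, threshold, size filter), 30 synthetic
cells per condition:

```r
lc3 <- recover_fold_change("lc3", n_cells = 30, base_seed = 0)
sprintf("control median %.1f, KO median %.1f, fold change %.2f",
        lc3$stat_control, lc3$stat_ko, lc3$ratio)
#> "control median 5.0, KO median 12.0, fold change 2.40"
```

The generator doubles the LC3 puncta rate in the knockout-like condition; the
detected fold change (2.40) recovers that twofold increase within the
pipeline's sampling noise. Compare groups the way the assays are analysed:

```r
set.seed(1)
g <- list(control = rnorm(30, 2.1, 0.4), ko = rnorm(30, 3.0, 0.5))
compare_groups(g, control = "control")
#> StatReport: t - statistic -9.4164 , p = 2.746e-13
#>   normality: all groups Gaussian
```

A command-line interface wraps the same functions
(`inst/cli/mitoquant {simulate, morpho, puncta, track, stats}`).

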