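---
title: "Quantifying mitochondrial morphology, mitophagy and dynamics with mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial morphology, mitophagy and dynamics with mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

# Overview

`mitoquant` implements a complete quantitative pipeline for mitochondrial
phenotyping from multi-channel fluorescence microscopy: 3D morphometry of
segmented mitochondria, puncta-based mitophagy readouts, a vesselness-based
live-cell tracking pipeline, and the statistical decision tree used to compare
experimental groups. Because studies of this kind rarely release raw image
volumes, the package ships a synthetic-scene generator with exact ground
truth, so every stage of the pipeline can be validated end to end without
external data. This vignette documents the models behind each stage, the
parameters that matter, and the design decisions taken where the methodology
left room.

# The synthetic scene model

A scene is one cell: a convex elliptical region containing

* **tubes** — mitochondria modelled as persistent random walks (persistence
  $p \in [0,1]$; $p = 1$ is a straight line) dilated to capsules of radius
  $r$: a voxel is foreground when its centre lies within $r$ of the walk
  polyline. This rule is unambiguous and converges as resolution increases.
* **puncta** — diffraction-limited objects (autophagosomes, mitolysosomes,
  MDV-sized vesicles). Point emitters seen through the microscope are
  PSF-shaped, so they are rendered directly as anisotropic Gaussians with the
  PSF's standard deviations.
* **patches** — Parkin-style accumulations: flat disks whose total area is a
  configurable fraction of the cell area. The area budget is deterministic
  (disk count and radius are derived from the budget), so the generated
  positive-area fraction equals the configured one exactly.
* **diffuse cytoplasm** — a low uniform emitter density inside the cell mask,
  giving puncta a positive local background against which peak-to-background
  ratios are well defined.

Rendering follows the camera physics in order: structure densities are
convolved with an anisotropic Gaussian PSF (default $\sigma_{xy} =
0.08\,\mu m$, $\sigma_z = 0.25\,\mu m$, approximating a super-resolution
spinning-disk system with $\approx 150$ nm lateral resolution), scaled to
expected photon counts (`photon_scale`), Poisson-sampled, then offset by the
camera `baseline` with additive Gaussian read noise. Default voxels are
$0.1 \times 0.1 \times 0.3\ \mu m$ (anisotropic z, as in confocal stacks).

Ground truth records every object *before* blur and noise: volume, principal
axis lengths and elongation computed from the rasterised voxel set, punctum
positions, amplitudes and cargo labels, and — for time-lapses — per-frame
identities and displacement vectors. Random draws are split into independent
streams per object class (cell shape, tubes, puncta, MDVs, patches, noise,
motion), so changing the puncta rate never perturbs tube geometry; the same
seed therefore gives *paired* control/knockout scenes that differ only in the
condition parameters. Stream seeds are scrambled with a multiplicative hash
and the generator is warmed up, so consecutive scene seeds draw decorrelated
values.

## Presets and the encoded effect sizes

Five presets encode the study conditions used throughout the tests
(`scene_preset(name, condition)`):

| preset      | readout                               | control | knockout-like | fold |
|-------------|----------------------------------------|---------|----|------|
| `lc3`       | LC3 puncta per cell                    | 6       | 12 | 2    |
| `parkin`    | Parkin patch area fraction of the cell | 0.002   | 0.05 | 25 |
| `cox8_48h`  | mCherry-only puncta per cell           | 1.5     | 15 | 10   |
| `morpho`    | tube length scale / MDV-sized objects  | 0.8 um, 1 | 2.2 um, 3 | — |
| `timelapse` | ten moving tubes for tracking          | —       | — | —    |

Only the fold changes are published; absolute per-cell rates are not. The
control rates above are chosen once as typical of the assays (a handful of
autophagosomes per fed cell; roughly one visible mitolysosome per healthy
cell; Parkin occupying a fraction of a percent of the cell footprint without
depolarisation) and are not revisited. Knockout-like values are control
values times the published fold change.

Other condition choices worth stating explicitly:

* Cells are single convex regions of realistic size (13–19 um across
  depending on the assay); the `cox8_48h` and `timelapse` presets use the
  larger fields so that 15 puncta or 10 moving tubes are not artificially
  crowded.
* The `timelapse` preset uses a mitochondrially targeted label with no
  cytosolic signal, 10 tubes placed at least 3.5 um apart, and object speeds
  drawn from a lognormal with median 0.08 um/s (log-sd 0.3), in the range
  reported for mitochondria in cultured cells at 2 s frame intervals. Motion
  is rigid per object with persistent direction and reflects off the cell
  boundary; fission and fusion are deliberately not simulated.
* In the `morpho` preset tubes are nearly planar (`z_wiggle = 0.05`), as in
  the thin lamellae of adherent cells. This matters because a 0.15-um tube
  wandering axially through a 0.3-um-spaced stack repeatedly crosses the
  mid-plane region where partial-volume effects thin the rasterised object,
  which fragments the segmentation of long tubes.

# 3D morphometry

Segmentation is intensity thresholding (a fixed value, or Otsu's method with
`"auto"`) followed by 26-connected component labelling and a *clean filter*
that removes components below `clean_min_voxels` (default 5), the stand-in
for the proprietary clean-up used in commercial software. The original
workflow chose thresholds manually per image; the fixed-threshold path
reproduces that workflow and is what the preset analyses use, applied
identically to all conditions.

Per object, the principal axis lengths are computed from the eigenvalues
$\lambda_i$ of the covariance of physical voxel-centre coordinates as
$a_i = 2\sqrt{5\lambda_i}$ — the full axes of the uniform ellipsoid with the
same second moments. Any constant would cancel in the elongation ratio

$$E = \frac{a_1}{(a_2 + a_3)/2},$$

the ellipsoid convention is used so the lengths themselves are physically
interpretable (a rasterised ellipsoid with semi-axes $(5,1,1)\,\mu m$ measures
$(10,2,2)\,\mu m$). A sphere has $E = 1$; a single-voxel object is defined to
have $E = 1$; a degenerate object with $a_2 = a_3 = 0$ is flagged. Size
classes use the published volume boundaries: MDV-sized below $0.03\,\mu m^3$,
network above $1\,\mu m^3$, intermediate otherwise. Per-cell summaries are the
median elongation over all objects, the total volume and the class counts.

Partial-volume physics limits what segmentation can recover in anisotropic
stacks: objects thinner than the z spacing rasterise to single-plane sheets
whose blurred intensity can fall below any threshold that still separates
touching structures. The validation suite therefore checks exact object-count
and IoU recovery on resolvable objects (diameter comparable to the z step)
and checks sub-resolution objects through their size-class statistics rather
than voxel-level overlap.

# Puncta assays

All 2D assays start from a maximum intensity projection. Background is
estimated by grayscale opening with a flat disc (rolling-ball style; default
radius 0.5 um, several punctum radii) and subtracted; the method used in the
original analysis is not specified, and opening was chosen because it removes
additive offsets exactly and never increases intensity. Puncta are
8-connected suprathreshold components with area *strictly greater* than
0.01 um^2.

The mitophagy-reporter classifier implements the published manual criterion:
a 1-um line is drawn through the punctum centroid (oriented toward the
brightest neighbouring mCherry pixel), the background is the mean of the two
line-end intensities, and the ratio is $\rho = (\text{peak} -
\text{bg})/\text{bg}$. A punctum is mCherry-only when $\rho_{mCherry} \ge 2$
("2:1 over background") and GFP is absent. Two published phrasings are
ambiguous and were resolved as follows, both configurable:

* "2:1 over background" is read as *background-subtracted peak at least twice
  the background* ($\rho \ge 2$), the stricter of the two readings.
* "lack of GFP fluorescence" is quantified as $\rho_{GFP} < 0.5$.
* the channel peak is taken within the central third of the line: the ends
  measure background, and a wider window would pick up neighbouring
  mitochondria rather than the punctum being scored (a human analyst
  implicitly does the same).

Cargo-selective MDV calling matches spot centroids across two channels by
greedy nearest-pair matching within 0.15 um (the measured size scale of these
vesicles, at or below the diffraction limit — hence centroid matching rather
than pixel overlap); matched pairs are dual-labelled, unmatched spots are
single-cargo MDVs. FWHM linescans subtract the profile minimum and measure
the distance between the half-maximum crossings bracketing the global peak,
with linear interpolation between samples; for a Gaussian profile the result
is $2\sqrt{2\ln 2}\,\sigma$. Spot density on mitochondria divides the number
of spot centroids on the mask by the mask area; ROI mean intensity is the
arithmetic mean within the cell mask.

# Live-cell dynamics

Time-lapses are first corrected for photobleaching by histogram matching:
each frame's intensities are rank-mapped onto frame 1's histogram, which
removes any monotone intensity decay exactly. Frames are then enhanced with a
multiscale Frangi vesselness filter for bright ridges (scales default to
1–2 px around the PSF width; $\beta = 0.5$; the structureness scale $c$
defaults to half the maximum Hessian Frobenius norm per scale). Before the
response is computed, voxels whose Hessian Frobenius norm falls below the
square root of the *maximum* Frobenius norm are zeroed — an efficiency gate
carried over from the original pipeline, implemented literally and
disableable (`gate = FALSE`); on count-scaled images the gated and ungated
responses agree on every voxel that passes the gate. The combined response is
normalised to $[0,1]$ and the semantic mask keeps everything above $10^{-5}$
(the published constant; it is assumed to apply to the normalised response).
Instances are connected components of the mask.

Skeletons are one-pixel-wide medial axes obtained by iterative thinning, with
branches traced between nodes (tips, degree 1; junctions, degree $\ge 3$,
with touching junction pixels clustered into a single junction). Every
degree-2 skeleton pixel belongs to exactly one branch, and branch lengths sum
physical steps. The package skeletonises in 2D and reduces 3D masks by
maximum projection first — the fast volumetric live-cell protocol is analysed
per frame in projection; the published 3D thinning variant is the natural
extension point.

Tracking links objects of consecutive frames by a global minimum-cost
assignment (Hungarian algorithm). The exact cost function of the original
tracker is not published; the documented stand-in is three normalised terms

$$c_{ij} = \frac{d_{ij}}{v_{max}\,\Delta t}
  + \frac{|V_i - V_j|}{V_i + V_j}
  + \frac{|a_{1,i} - a_{1,j}|}{a_{1,i} + a_{1,j}},$$

with links beyond the speed gate $d > v_{max}\Delta t$ forbidden, ties broken
by distance then label, and no gap closing: a missed detection ends the track
(documented extension point). Track metrics are path length (sum of
frame-to-frame centroid displacements, not net displacement) and mean speed =
path length / elapsed time.

# Statistics

The group-comparison tree reproduces the published workflow:

1. **ROUT outlier removal** per group (single-group location model; the
   regression form is out of scope). Robust centre = median; robust scale =
   RSDR, the 68.27th percentile of absolute residuals corrected by
   $n/(n-1)$; each point gets a t-like statistic with $n-1$ degrees of
   freedom and points are screened from the most extreme inward against a
   Benjamini–Hochberg-style boundary at rate $Q$ (default 0.01, the method's
   convention; the publication does not print $Q$).
2. **Shapiro–Wilk normality** per group; constant samples are non-normal by
   definition.
3. All groups Gaussian: unpaired two-sided **Student's t test** (pooled
   variance, with a Welch switch) for two groups, **one-way ANOVA** for
   three or more, followed by **Dunnett** against a named control (via the
   multivariate-t formulation) or **Tukey** otherwise. Any group
   non-Gaussian: **Mann–Whitney** or **Kruskal–Wallis + Dunn** with mid-ranks,
   tie-corrected variance and Holm adjustment (the publication names Dunn's
   test but not its correction).
4. **Per-replicate normalisation** divides each observation by its
   replicate's control mean, so the control mean is 1 within every replicate.

The report records every branch taken, the removed outliers and the
normality results, and is a pure function of (data, configuration).

# Validation strategy and what it shows

The test-suite works almost entirely from (scene, ground truth) pairs:
fold-change recovery through the complete detection pipelines (LC3 x2,
Parkin-area x25, mCherry-only x10, each on 30 synthetic cells per condition,
scene seeds 1–60), analytic morphometry oracles (rasterised ellipsoids and
capsules evaluated independently of the generator), FWHM against the Gaussian
closed form, tracking link recall and speed recovery against ground-truth
tracks, Monte-Carlo calibration of the statistical tree (type-I error, ROUT
false-flag rate, Shapiro–Wilk behaviour) and a Monte-Carlo oracle for the
Dunnett adjustment. Problem sizes (128–192 px fields, 6–10 z planes, 8–20
frames, 30 cells per condition, 60–1000 Monte-Carlo replicates) were chosen
as the smallest at which the statistical assertions are stable.

What passing does **not** show: the generator's Gaussian PSF and rigid
per-object motion are idealisations — there is no spectral bleed-through, no
cristae substructure, no fission/fusion, no deconvolution artefacts and no
spatially varying background, so recovery rates here bound from above what
the same pipeline would achieve on real acquisitions. Numerical edge cases
are handled explicitly: empty scenes and masks propagate as empty results
with warnings rather than errors; degenerate elongations are flagged;
all-background segmentations warn; singleton tracks have undefined metrics;
constant samples fail normality by definition.

# Known limitations

* Skeletonisation is 2D (projections); 3D thinning is not implemented.
* No track gap closing; occlusions and missed detections split tracks.
* The Frobenius gate presumes count-scaled data: on images normalised to
  $[0,1]$ the gate threshold $\sqrt{\max \|H\|_F}$ exceeds every norm and
  suppresses the whole response; disable the gate for such data.
* ROUT is the single-sample location variant only.
* OME metadata is written to a companion XML file rather than embedded in
  the TIFF (the TIFF writer available to R cannot set the description tag);
  readers that require in-file OME-XML should convert with external tools.
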