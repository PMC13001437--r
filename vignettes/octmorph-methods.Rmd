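---
title: "Skeleton-based OCT layer morphometry: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-based OCT layer morphometry: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`octmorph` is a post-segmentation analysis engine for labeled murine OCT
B-scans. It takes per-pixel layer masks (from any segmentation source —
a trained network, manual annotation, or the built-in phantom), plans and
extracts crops perpendicular to the tissue midline, profiles every layer's
medial axis, applies rule-based quality control, aggregates features to eye
and mouse level, and runs nonparametric group statistics and hierarchical
clustering for focal-lesion discovery. Segmentation itself is out of scope:
the ingest seam accepts any single-channel 8-bit mask using the
10-value label scheme (background 0, IPL/INL/OPL/ONL/ELM/ISOS/RPE/CHR 1–8,
retinal detachment 9).

# Crop geometry

A full B-scan's tissue mask is reduced to a midline axis with one pixel per
column. We use the smoothed per-column centroid of the tissue mask rather
than a thinning-based skeleton: for a vertically convex tissue band the
column centroid *is* the medial axis, while topological thinning of a
~240 px thick curved band wiggles by several pixels around it. The axis is
smoothed with a centered moving average (`crop.tangent_window`, default
31 px) and tangent angles are taken over a window-length baseline —
adjacent-pixel differences alias the 1-px staircase of the rasterized
boundary and oscillate by about ±1 degree.

Crops (default 256×400 px, centered at columns 256, 512 and 768 of a
1024-px scan) are extracted by inverse mapping: each crop pixel pulls from
`center + u·t + v·n` where `t` is the unit tangent and `n` its
perpendicular. Intensities are sampled bilinearly; labels by nearest
neighbor, so a crop can only contain label values present in the source.
Offsets are integer about the center pixel, making a rotation-0 crop exact
slicing. Crop height is symmetric about the axis point (the depth window is
centered on the tissue midline).

Crop centers are registered to the optic nerve head as
`onh_dx = x_scale·crop_center_x − onh_x`, `onh_dy = scanline_y − onh_y`,
in fundus pixels. The fundus/OCT lateral scale `registration.x_scale`
defaults to 1 and should be set to the instrument's true ratio when known.

# Skeleton metrics

Each layer mask is skeletonized by Zhang–Suen thinning followed by a
minimal-skeleton reduction (sequential deletion of connectivity-preserving
non-endpoint pixels, Yokoi connectivity number 1). The reduction matters:
raw Zhang–Suen output contains staircase "elbows" whose pixels have three
neighbors and would read as spurious junctions — on a clean curved band we
observed 16 false junction events before the cleanup and none after.

Two boundary-handling choices are deliberate:

* **Left/right image edges are tissue cuts, not anatomy.** Masks are
  extended sideways by replicating their edge columns before both the
  thinning and the distance transform. Without this, the medial axis grows
  diagonal corner tails where a layer runs off the crop and thickness drops
  toward zero at the edges, biasing layer means ~10% low.
* **Thickness is read at the distance-transform ridge.** Thinning can park
  the axis 1–2 px off the true medial line on slanted boundaries; the
  thickness at a skeleton pixel is `2 ×` the maximum Euclidean distance to
  background within a 7-px vertical window centered on the pixel. On
  rectangles this is exact; on gentle wedges it tracks the analytic ramp
  within 2 px. Thickness of odd-height layers reads one pixel high (the
  pixel-center-to-pixel-center effect of doubling a distance to the nearest
  background *pixel*); all tolerances in the tests account for this.

Junction pixels are skeleton pixels with ≥3 neighbors (8-connectivity);
8-adjacent junction pixels merge into one junction event, and the event
count is the layer's bifurcation count. Endpoint branches shorter than
5 px that terminate at a junction are pruned as thinning noise; structural
spurs survive because a protrusion only bends the medial axis once it
extends on the order of the layer's half-thickness — the phantom's
spur lesions are therefore generated with prong length comparable to the
layer thickness.

Local angles come from an 11-px least-squares line fit per branch pixel
(ends truncated); all-`dx=0` windows are 90°, all-`dy=0` windows 0°,
otherwise `atan(slope)`, with an `atan2`-of-mean-displacements fallback
(5 px per side) for degenerate fits. The sign convention (positive =
descending in image coordinates) is internal: exclusions and the inflection
formula use magnitudes only. Inflections are sign changes of the per-column
mean angle; at each, the means of the 11 columns before and after give
`angle = 180 − |m_pre + m_post|`. Events whose flanking window mean
absolute angle lies in [80°, 90°] are excluded (the vertical-exclusion rule
is applied to window means, not individual pixels, since its purpose is to
focus on horizontal inflections), and remaining angles are counted into the
bins `<165`, `[165,170)`, `[170,173)`, `[173,175)`, `[175,177)`; values at
or above 177° stay uncounted.

Domains are 8-connected components (connectivity chosen to match the
skeleton's 8-connectivity; a minimum-size filter is available but defaults
to 0). Normalized thicknesses divide retina layers by TRT
(IPL+INL+OPL+ONL+ELM+ISOS) and RPE/CHR by the sclera total (RPE+CHR).
The micron conversion utility scales x-displacements by the lateral
anisotropy factor 1.62 before rederiving the hypotenuse; it is a
reporting-time utility and is not applied to the pixel-domain features.

Per-crop profiles are ≤ crop-width readings per layer (one aggregate per
x column, arithmetic mean when a column holds several skeleton pixels).

# Quality control

A crop is *flagged* when any layer has ≥2 domains. With fewer than 8
segmented layers it *fails* when ≥2 layers are multi-domain and their
average largest-domain ratio is below 75%; with all 8 layers it fails below
98% for ≥3 multi-domain layers, or below 85% for exactly 2 (read as
"exactly 2" since three or more trigger the 98% rule). Crops with ≥6 total
bifurcations fail regardless; the bifurcation filter is applied per image,
before deduplication. All cut-offs are strict (`<`), so a ratio exactly at
a boundary passes; the boundary sweeps in the acceptance suite pin each
one. The optic-nerve-head crop (midline scanline, center position) is
excluded before QC. Eyes pass when ≥5 crops pass covering ≥2 scanline
locations. Deduplication keeps one crop per
(mouse, eye, timepoint, scanline, position): fewest QC flags, then highest
manual quality grade, then smallest image path — a deterministic,
idempotent selection (the tie-break order is this package's choice).

# Statistics

Inference is at the mouse level: image features are averaged within eyes
(mean/SD/SEM over deduplicated passing crops) and across a mouse's
available eyes. Two-group comparisons use the two-sided Wilcoxon rank-sum
test with Cliff's delta and BH correction across features; multi-group
comparisons the tie-corrected Kruskal–Wallis test with
`ε² = H(n+1)/(n²−1)` and Dunn's post hoc z-tests, BH-adjusted within each
feature's pairwise family (cross-feature FDR is applied separately at the
omnibus level). SEM volcano tables use
`log2((SEM_a + 10⁻⁴)/(SEM_b + 10⁻⁴))` against `−log10 p` of the matching
rank-sum test; the offset keeps zero-variance features finite (two zero
SEMs give a fold change of exactly 1).

The rank-sum p-value defaults to the tie-corrected normal approximation
without continuity correction rather than the exact distribution
(`stats_config(exact = TRUE)` switches). Two reasons: at n = 4 per group
the exact test's smallest attainable two-sided p is 2/70 ≈ 0.029, making
its realized per-test rejection rate at α = 0.05 markedly conservative
(0.029 rather than the asymptotic 0.057), and the uncorrected normal form
preserves the algebraic identity between the two-group Kruskal–Wallis
statistic and the squared rank-sum z, which the test suite uses as an
oracle. Correlation heatmaps use Spearman correlation (consistent with the
rank-based tests); PCA is computed on z-scored features with eyes (or
mice) as observations. Plots are deliberately optional — the analysis
surface is the CSV tables.

# Clustering

Per-crop feature vectors are z-scored (full-table mean/SD, constant
features dropped), clustered with Euclidean distance and Ward linkage, and
cut at 4 clusters by default (detachment, degeneration, RPE-defect and
focal-lesion groups are the archetypes such a cut is meant to separate;
the cut and the linkage are configurable). The default 12-feature subset —
ONL thickness mean/SD/max/range, TRT, sclera total, total area, total
bifurcations, total domains, detachment area and fraction, and the summed
sub-173° inflection count — covers the lesion-sensitive measurement
families; it is a configuration default, not a fixed contract.
Cluster-vs-phenotype validation treats membership in a cluster as the
positive call: sensitivity TP/(TP+FN), specificity TN/(TN+FP).

# The phantom

The generator emulates what the downstream stages need to be testable:
eight stacked layers under a shared sinusoidal upper boundary (amplitude
30 px, period 1024 px by default — the smooth globe curvature the crop
stage must correct), per-layer mean grey levels with Gaussian intensity
noise (labels are never noised: masks are the pipeline's input contract),
and five lesion kinds — detachment (an RD band between ISOS and RPE),
focal thinning (cosine profile), domain breaks, bifurcation spurs
(a 7-px-wide prong protruding into the layer above) and regional
gradients. Default layer thicknesses (IPL 50, INL 30, OPL 15, ONL 60,
ELM 8, ISOS 25, RPE 12, CHR 40 px) give realistic murine proportions at
the instrument's scale. Cohorts draw a per-mouse, per-layer log-normal
thickness multiplier (sdlog 0.05, ≈5% between-mouse CV — a typical
biological coefficient of variation for murine ONL thickness) and a
per-image multiplier (sdlog 0.02) for acquisition repeatability; no
distributional model of biological variability is claimed by the source
science, so this noise model is a stand-in chosen once. Ground truth
(exact per-column label row-counts and the lesion inventory) is emitted
with every scan, and identical (config, lesions, seed) reproduce
bit-identical files.

What the phantom does not emulate: OCT speckle physics, vascular shadows,
segmentation-network errors, real fundus photographs (the ONH is a filled
disk on a 1024² canvas), or pathology beyond the five lesion archetypes.
Passing tests therefore demonstrate that the measurement, QC and inference
machinery is correct and calibrated on known geometry — not that any
particular biological effect size will be recovered from real scans.

# Numerical choices and conventions

* Coordinates are 1-based, `x` = column increasing rightward, `y` = row
  increasing downward, matching R matrix indexing.
* Quartiles use linear interpolation (R type 7); the per-crop thickness SD
  is the population form.
* Null-coded features are excluded pairwise from aggregation; an eye's SEM
  with a single finite reading is 0, with none `NA`.
* Degenerate stats inputs: a feature constant in both groups reports
  p = 1, delta = 0, and is flagged; features with undefined SEM are
  dropped from volcano tables with a warning.
* Empty layer masks yield empty skeletons (not errors) and `NA` thickness
  statistics; QC treats an absent layer as area 0.

# Problem sizes used in the checks

The calibration checks run at sizes chosen to estimate their quantities
tightly while staying desk-scale: type-I control uses 200 null cohorts of
250 independent phantom-model features at 4 mice per group (50,000 tests;
binomial SE ≈ 0.001 on the rejection rate); effect recovery uses 100
seeded cohorts at 4 mice per group; clustering separation uses 30 clean
plus 30 detachment crops through the full image pipeline; and the
end-to-end run uses 2 groups × 4 mice × 2 eyes × 3 scanlines × 2
replicates (96 B-scans, 288 crops).

# Known limitations

* Thickness carries the +1 px odd-height bias described above; comparisons
  between groups are unaffected (the bias is common to both).
* The medial-axis spur response is geometric: protrusions much shallower
  than the layer half-thickness do not branch the skeleton and are instead
  visible in the thickness SD and inflection features.
* ~Width readings per layer per crop: a 256-px crop yields at most 256
  per-column readings; pipelines that resample to finer grids will report
  more readings per crop for the same anatomy.
* The eye gate refuses, rather than down-weights, eyes with sparse spatial
  coverage; with instrument protocols that acquire fewer locations per
  eye, relax `qc_config(eye_min_passing_images, eye_min_ylocations)`.
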