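---
title: "Slice-based morphometry of rodent knee soft tissues: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-based morphometry of rodent knee soft tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiflemorph)
```

## The measurement problem

Rodent knee (stifle) ligaments and menisci can be segmented from high-field
MRI and exported as triangle meshes in millimetres. The quantities of
scientific interest are simple but must be defined operationally:

* the **midsubstance cross-sectional area** of each ligament, i.e. the
  typical transverse area away from the flared bony insertions;
* **regional meniscus heights and widths** at the anterior horn, central
  body and posterior horn;
* ligament CSA **normalized by the tibial plateau footprint**, a bone-size
  proxy that puts rats and mice on one scale.

This vignette records the model behind each measurement, the tunable
parameters, the numerical choices made where the protocol leaves the design
open, and what the synthetic-data tests do and do not establish.

## Ligament CSA

A mesh is converted to a point cloud (its welded vertex set — deterministic,
no resampling rule to document), centred, and rotated so the first principal
direction of the covariance maps to +z. Two conventions make this
reproducible: the axis sign is chosen so the longer tail of the z
distribution about its median is positive, and the remaining principal
directions become x and y in a right-handed frame (in-plane rotation does
not change areas). A cloud whose first-to-second principal variance ratio is
below 1.5 carries a `near_isotropic` warning instead of an error, since
areas remain computable even when the axis is poorly determined.

Slices are contiguous half-open bins `[z_min + k*h, z_min + (k+1)*h)` of
thickness `h` = 0.1 mm (rat) or 0.05 mm (mouse), matching the isotropic
voxel sizes of the two imaging protocols; a point exactly at the maximum
joins the last bin so every point is assigned once. Each slice is flattened
by discarding z — after axis alignment the slice normal *is* z, so no
per-slice plane fit is needed — and its CSA is the shoelace area of the 2D
convex hull. The hull was chosen because ligament sections are near-convex
and the estimator is deterministic and parameter-free; an alpha-shape would
handle concave sections but introduces a radius parameter with no stated
value. Slices with fewer than 3 points (or a collinear projection) get a
*missing* CSA, never zero, and never enter any mean.

The midsubstance is the middle 50% **of the axial extent** (25th to 75th
percentile of the occupied z-range, bounds inclusive), not the middle half
of the slice list: the extent rule is robust to partially filled end bins.
The reported CV is the n−1 standard deviation over included slices divided
by their mean, in percent.

Known property: because the hull keeps only extreme points, zero-mean
surface noise *inflates* the estimate. At sigma = 0.005 mm on a rat-scale
tube at the generator's vertex density the measured inflation is about 4.6%
(Monte-Carlo over 20 seeds, frozen in the test suite). Smooth segmentations
(upstream Gaussian filtering) keep this small in practice, but the hull
estimator should not be used on raw noisy point clouds.

## Meniscus regional measures

The meniscus is aligned to an anatomic frame: the smallest-variance
principal direction becomes z (superior–inferior); a circle is fitted to the
projected arc (Kasa algebraic fit) and the in-plane bulge — the direction
opposite the arc's largest empty angular interval, i.e. opposite the C
opening — becomes +x for a lateral meniscus and −x for a medial one
(right-knee convention: +x lateral, +y anterior). The z sign is set so the
wedge's wide base (the half of the cloud with the larger in-plane radial
spread) faces −z, the tibial side. The largest-gap rule was chosen over the
mean-unit-vector direction because it is insensitive to uneven surface
sampling; with the synthetic generator it recovers the frame to well under
half a degree.

Regions follow the middle-three-slice protocol: the central region is the
three adjacent coronal (y) bins centred on the median y of the arc apex
(the extreme ±x tenth of the cloud), keeping only bulge-side points; the
anterior and posterior horns are the three adjacent sagittal (x) bins
centred on the median x of the full cloud, split by the sign of y. The slice
thickness reuses the species increment (0.1 / 0.05 mm) — the protocol never
states a separate meniscus slice thickness, and the voxel grid makes this
the natural choice.

Each 2D slice is summarized by **ten equally spaced stations**: the
horizontal extent is divided into ten bins whose vertical point extents are
the station heights, and symmetrically for widths. The slice value is the
**maximum** station value and the region value the mean of its three slices.
The protocol text asks for ten measurements per slice while the figure
legend records maxima; computing all ten stations and summarizing by the
maximum reconciles both, and the per-station table is kept in the output for
sensitivity analysis. Note the direction of the refinement property: a
coarse station is the union of two nested fine stations, so *doubling* the
station count can only keep or lower the slice maximum — the extent of a
union bounds the extents of its parts from above.

## Footprint normalization

The tibial plateau is a single-slice axial voxel mask; its area is the
segmentation volume divided by the voxel height, `count * dx * dy`. A mask
spanning several axial slices is accepted with a warning under the same
volume-over-height contract. The planar-trace alternative (for microCT
validation workflows) is the shoelace area of a simple polygon times the
squared pixel size; self-intersecting traces are rejected.

Normalization is **per specimen** — each knee's CSA over its own footprint,
in percent — and group statistics are taken over those ratios
(mean-of-ratios). The ratio-of-group-means is also attached as an audit
attribute because published tables do not say which convention they use; the
two differ in the second decimal for some tissues.

## Statistical battery

All rank procedures use midranks. Kruskal–Wallis applies the standard tie
correction and the chi-square approximation on k−1 df; all-tied data return
H = 0, p = 1. The two-sample rank-sum test is exact (Wilcoxon null
distribution) for combined n ≤ 20 without ties and otherwise uses the
normal approximation with tie and continuity corrections. Post hoc pairwise
comparisons default to rank-sum tests with Bonferroni correction over the
number of pairs; `tukey_on_ranks` (Tukey's HSD on the pooled midranks) is
available because parametric Tukey tests are sometimes quoted after a rank
omnibus, but a rank-based post hoc is the internally consistent default.

The aligned rank transform (ART) two-way ANOVA aligns responses per effect
with **cell-means estimates** (residual plus the effect's own estimate),
ranks the aligned values, and runs a balanced two-way factorial ANOVA on the
ranks, reporting only the aligned-for effect. The alignment identity (each
effect's aligned responses sum to zero) is checked on every call. The
implementation requires a balanced design: the side × region meniscus tables
are balanced by construction, and cell-means alignment is ambiguous for
unbalanced data. Specimen-level pairing (a repeated-measures error
structure) is deliberately not modelled; cells are treated as independent,
which matches the degrees of freedom conventionally reported for these
designs.

Agreement statistics: Bland–Altman bias with 1.96-SD limits and a
differences-on-means slope as the proportional-bias probe, and the two-way
random-effects, absolute-agreement, single-measure ICC computed from the
two-way mean squares
`(MSR − MSE) / (MSR + (k−1) MSE + k (MSC − MSE) / n)` with k = 2 raters.
Zero between-subject variance makes the ICC undefined and is reported as
such rather than coerced to a number. Alpha is 0.05 throughout; Bonferroni
adjustment is `min(1, p*m)`.

## The synthetic world

`generate_cohort()` emulates the study's cohorts so the pipeline is testable
without imaging data. Its defaults *are* the stated world and are not tuned:

* **Scales.** Tissue-mean ligament CSAs, meniscus regional widths/heights
  and plateau areas come from the published species means shipped in
  `inst/extdata/tissue_presets.csv` (rat CSAs 0.17–0.35 mm², mouse
  0.029–0.054 mm²; plateaus 33.35 / 5.67 mm²).
* **Scatter.** Between-specimen size scalars are lognormal with CV 25%
  (configurable), inside the 16–40% range observed across rodent ligaments;
  lognormal because sizes are positive and multiplicative.
* **Ligaments** are swept polygonal tubes (≥ 64-gon) with a flared area
  profile: constant `a0` over the middle half, ramping to 1.5 a0 at the
  insertions (3 a0 in the trimming stress test). Section semi-axes carry the
  polygon-to-ellipse correction `sqrt((2pi/n)/sin(2pi/n))`, so "truth" is
  the area of the polygon actually built, exactly. Vertex spacing is a
  quarter of the slice increment, tightened to perimeter/40 for thin tubes;
  a request too coarse for 0.5% section fidelity is refused with the
  required spacing. Lengths are 4 mm (rat) and 2 mm (mouse) — long enough
  that boundary slices straddling the flare onset perturb the trimmed mean
  by well under 1%.
* **Menisci** are wedge sections swept along a circular arc. The default
  span is 320 degrees: the 40-degree gap between horn tips makes the
  mid-body sagittal slices cut the horn limbs nearly transversely, which is
  what the slicing protocol geometrically assumes (horn tips wrap toward
  the tibial eminences). Regional fields use a smoothstep in |theta| that
  reaches the horn value exactly at a quarter of the span — the angle where
  the median-x rule lands for an arc sampled uniformly in angle — with zero
  slope there and at the apex, so slices adjacent to a measurement station
  see almost exactly the station's field value. Ground truth is the field
  value at those nominal angles (`meniscus_truth()`). Residual measurement
  bias is the small positive obliquity of a planar cut through a curved
  band, about +2–4% for widths at this span; the 5% recovery criterion
  budgets for it. Menisci are generated with a random rigid perturbation up
  to 15 degrees so the alignment code is genuinely exercised.
* **Plateaus** are rasterized discs occupying the voxels nearest the grid
  centre; the achieved (not requested) area is recorded as truth.

What a green synthetic test establishes: the geometry code recovers known
truths under rotation, scaling, mirroring and realistic size scatter, and
the statistical battery has correct null behaviour at the study's group
sizes. What it does not establish: robustness to real segmentation artefacts
(stair-stepping, partial-volume boundaries, meniscal ossicles — an
ellipsoidal-void extension was considered and left out), non-convex ligament
sections, or menisci whose arcs deviate strongly from the circular-wedge
idealization.

## Numerical notes and limitations

* Vertex welding is exact bitwise matching; epsilon merging could collapse
  thin mouse-scale structures (~0.03 mm² sections) and is deliberately
  avoided.
* STL I/O is binary (80-byte header, uint32 count, 50 bytes per facet) with
  an ASCII reader; coordinates round to float32 on write, the format's
  precision.
* Ties at the 25/75% extent boundaries are included in the midsubstance;
  points exactly on a bin's upper edge belong to the next bin except at the
  global maximum.
* The Kasa circle fit of an annular band lands slightly outside the
  centreline radius; only the fitted *centre* is used downstream, so this
  bias is harmless.
* Exact rank-sum enumeration is limited to combined n ≤ 20; beyond that the
  tie-corrected normal approximation differs from the exact tail by < 0.01
  at n = 20.
* The pipeline treats every input mesh as millimetre-scaled; STL carries no
  units, and a mis-scaled mesh will silently produce wrong areas.
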