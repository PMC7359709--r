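---
title: "Quantifying thrombus on tubular grafts from microCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thrombus on tubular grafts from microCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftCT)
```

## The measurement problem

Ex vivo hemocompatibility testing exposes tubular graft biomaterials (4--5 mm
inner diameter) to flowing non-anticoagulated blood and quantifies platelet
and fibrin accumulation radiometrically. Those endpoints say nothing about the
*physical* shape of the deposit. Scanning the fixed graft by microCT yields a
voxel volume (typically 512 x 512 in-plane at 60 mm field of view, i.e.
60/512 = 0.1171875 mm isotropic voxels, 165--369 slices) in which either the
open lumen or the thrombus has been rendered radiopaque, depending on the
material's water absorption:

* **PVA** hydrogel absorbs aqueous stain, so a curable radiopaque cast is
  perfused instead: the *lumen* is bright (`lumen_opaque`).
* **ePTFE** is hydrophobic and takes up no iodine stain, while the thrombus
  does: the *thrombus* is bright, the lumen stays dark (`thrombus_opaque`).
* **Collagen-coated ePTFE** is processed like ePTFE but analyzed for four
  nested materials -- dark lumen, stained thrombus, graft wall, outermost heat
  shrink tubing (`four_material`).

graftCT reproduces this workflow end to end and, because no public scan data
exist for it, ships a first-class synthetic phantom generator whose ground
truth is known exactly, so every stage can be validated quantitatively.

## Segmentation model

The segmentation primitive is the *masking wand*: the 4-connected set of
pixels, contiguous to an operator's click, whose intensity lies in a
user-specified inclusive range ([masking_wand()]). Segmentation is strictly
2D per cross-sectional slice; 3D growing is deliberately avoided because
partial-volume bridges between slices can make a region leak along the tube.
Slice-to-slice operation is automated by [propagate_seed()]: the next seed is
the in-mask pixel nearest the previous mask's centroid, which stays inside
even crescent-shaped regions. If the propagated seed lands out of range the
implementation falls back to the largest in-range component that overlaps the
previous mask, or, lacking one, the largest component not touching the image
border (interior graft materials never touch the border; the background
always does). A fully occluded cross-section yields an empty mask and
traversal continues: occlusion is a real outcome, not an error.

Boundary voxels mix two materials and take intermediate "medium gray"
intensities. The calibration rule therefore selects the target's core range
*plus one layer of medium-gray border pixels* ([include_border_layer()], an
intensity-gated one-pixel dilation). The gray band is an explicit calibration
input because trained operators choose it by eye; it is never inferred from
the image.

For the four-material samples, materials are claimed sequentially -- lumen,
shrink tubing, wall -- each taking only unclaimed pixels, and the *remaining
material inside the wall is the thrombus*: per slice, the wall mask is
hole-filled and the interior minus all explicit labels becomes thrombus
([segment_four_material()]). Slices where the wall fails to close around the
lumen are flagged in the result metadata rather than aborting the sample.

## Morphometry

Areas are voxel counts times the in-plane pixel area; volumes are summed per
slice so that the identity `volume == sum(area_per_slice) * dz` holds exactly,
ulp for ulp. Length follows the slice-numbering span convention: (last
occupied slice - first occupied slice + 1) x dz, *including* interior
zero-area slices -- an occluded segment is still graft length, and this is the
convention that matches caliper-measured physical length. The headline metric
is the average cross-sectional area, volume / length. For thrombus-opaque
samples the luminal volume is the caliper cylinder pi (d/2)^2 L minus the
measured thrombus volume ([lumen_from_subtraction()]); the measured thrombus
span provides the length normalization, as it is the only image-measured
length available in that mode. Per-slice variability is summarized as mean
+/- sample (n-1) SD over the occupied span (the convention is this package's
choice; the source workflow does not state one).

## The phantom generator

[generate_phantom()] renders a straight circular tube along the slice axis.
Key design choices:

* **Partial volume by supersampled occupancy, not blurring.** Each voxel is
  subdivided `supersample`^2 times in plane (default 8, i.e. occupancy
  resolved to 1/64); the voxel intensity is the occupancy-weighted mean of
  material levels. This manufactures exactly one layer of medium-gray border
  pixels -- the situation the calibration rule targets -- with no other
  smoothing.
* **Thrombus shape.** A mural deposit: the open lumen is a disk of radius
  rho(z) = sqrt(r_in^2 - A_T(z)/pi) offset from the axis by
  `eccentricity * (r_in - rho)` along a seed-drawn direction, so the per-slice
  deposit area matches the target profile A_T(z) analytically. The default
  eccentricity 0.5 gives a moderately wall-attached crescent while keeping the
  open-lumen boundary clear of the wall, so boundary voxels mix at most two
  materials and midpoint calibrations cut them exactly. The axial profile is
  a clipped sinusoid (baseline + amplitude, period in mm) emulating the
  axial variability of a single deposit. No quantitative thrombus-shape
  statistics exist to fit; the eccentric annulus is a stated modeling
  convenience.
* **Truth labels** come from majority sub-voxel occupancy, with ties assigned
  to the enclosed material (lumen, then thrombus, then wall, then shrink) --
  the same convention as the border-layer rule, which assigns the gray edge
  to the selected target.
* **Axis placement.** The tube axis sits exactly on the central voxel of an
  odd grid. Defaults: 4 mm ID, 5 mm OD, 0.1171875 mm voxels, so printed-scale
  numbers are realistic (a 4 mm lumen is ~34 voxels across).
* **Randomness.** One seeded generator; the sinusoid phase and deposit
  direction are drawn first, noise afterwards, so geometry is bit-stable when
  only `noise_sigma` changes. Identical specs give bit-identical phantoms.

### What the phantom does and does not emulate

It reproduces the three contrast situations, partial-volume border pixels,
additive Gaussian noise, axial thrombus variability, and occlusion. It does
*not* model beam hardening, ring artifacts, scatter, polychromatic physics,
non-circular or tortuous grafts, or anatomically realistic implants. Passing
the phantom validations therefore demonstrates correctness of the *analysis*
under ideal acquisition, not robustness to scanner artifacts.

## Numerical behavior worth knowing

**Binary voxelization quantizes areas.** A disk of radius r = 17.07 voxels
(4 mm at 117 um) cannot be represented by whole pixels with arbitrary
accuracy: the coverage-threshold pixel count deviates from pi r^2 by an
amount that fluctuates with radius and sub-voxel placement (roughly -5 to +15
voxel-areas across 4--5 mm diameters). With the default construction the
deviation is +1.94 voxel-areas, constant along the tube, and the per-slice
lumen + thrombus conservation residual sits exactly there -- within the
2-voxel-area acceptance bound used in the tests. Supersampling refines the
*occupancy* (the gray levels), which converges to the analytic mixture; it
cannot remove the label-count quantization, which converges to the exact
coverage-threshold count instead. The tests assert each of these properties
for what it is.

**Calibration convention.** Operator calibrations built by
[phantom_analysis_mode()] place the border band at inter-material intensity
midpoints, with equal mixes going to the enclosed material (enclosing bands
start just inside their midpoints). When a target faces two materials of
different intensity, one inclusive range cannot cut both interfaces at 50%
occupancy; the band is keyed to the nearest-intensity neighbor, which is
exact on the dominant interface and validated against phantom ground truth
(recovery within ~2.5% at the default deposit size) -- the same
calibrate-then-validate-against-known-volumes logic the original workflow
applies to its human operators.

**Thin deposits.** A deposit whose local thickness approaches one voxel is
swallowed by partial volume: majority-thrombus voxels at triple boundaries
(lumen/thrombus/wall) fall between calibration bands and are lost. Recovery
validation therefore uses a well-resolved deposit (per-slice area 6.49 +/-
1.19 mm^2, the reported doubly-measured condition, several voxels thick);
deposits of ~1--2 voxel thickness are systematically underestimated by any
intensity-threshold segmentation at this resolution. This is a real
limitation of the method, not only of the phantom.

**Statistics.** The length validation uses a fit constrained through the
origin with the *uncentered* R^2 = 1 - SSres / sum(y^2) (the centered
coefficient can be negative and is undefined in intent for forced-origin
fits) and an F test on (1, n-1) df. Group correlations are ordinary
least-squares with intercept; "ANOVA" significance is the single-predictor
regression F test, F = R^2 (n-2)/(1-R^2) on (1, n-2) df, with strict
inequality at the alpha boundary. No multiple-testing correction is applied
across groups, matching the source workflow.

## Problem sizes used in the shipped validations

The test-suite and acceptance-script studies are sized to run comfortably on
one CPU: the length validation uses 24 noise-free phantoms spanning 20--40 mm
(true lengths constructed as exact slice multiples); conservation uses three
8 mm four-material phantoms; recovery uses 6 mm phantoms of every mode, clean
and at noise SD = 10% of the minimum inter-material contrast; the type-I
calibration uses 1000 null simulations of n = 100. These sizes are choices,
not limits; every study scales linearly with slice count.

## Conventions

Slice indices are 1-based and ranges inclusive throughout, as usual in R.
Axis 1 is the graft's long axis; in-plane axes are row, col. Intensities stay
on their native scale -- no automatic normalization, since masking ranges are
calibrated in image units. TIFF stacks carry spacing in a JSON sidecar
(`{"spacing_mm": [dz, dy, dx]}`) because TIFF has no standard z-spacing tag;
NIfTI carries spacing in `pixdim`. The `tiff` package stores float samples
only on [0, 1], so float volumes belong in NIfTI; integer volumes round-trip
through either format bit-exactly.
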