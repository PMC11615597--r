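---
title: "Quantifying 4D aortic motion from segmentation masks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 4D aortic motion from segmentation masks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-resolved (cine) 3D imaging of the thoracic aorta, segmented into one
binary mask per cardiac phase, contains far more information than the
diastole-versus-systole comparisons usually reported: the vessel translates
by up to ~13 mm as the contracting heart pulls on the aortic root, and its
lumen distends by ~1-2 mm with each pressure pulse. `aortamotion` turns a
4D mask series into three per-vertex surface maps for every cardiac phase —
displacement, diameter, and diameter change — and summarises them as motion
curves over a user-chosen region of interest (ROI), typically the ascending
aorta (AAo) between the sinotubular junction and the mid arch. The package
consumes masks from any source (deep-learning segmentations, manual
contours, synthetic phantoms); image acquisition and segmentation are out of
its scope.

## Pipeline overview

1. **Surface extraction** (`extract_surface`). Each phase's binary mask is
   pre-smoothed with an isotropic Gaussian (default sigma = 0.8 voxel), and
   the 0.5 iso-surface is triangulated by marching tetrahedra over the
   Freudenthal (six-tetrahedra) decomposition of every grid cell, which
   yields a watertight, consistently oriented mesh without case tables.
   Ten iterations of Taubin smoothing (lambda = 0.5, mu = -0.53) remove the
   residual staircase while changing the enclosed volume by well under 2%.
   Vertices are mapped to world millimetres through the NIfTI affine
   (0-based voxel centres, RAS+).
2. **Registration** (`register_pair`). The end-diastolic reference surface
   (always phase 0) is registered directly and independently to each other
   phase — never chained frame to frame, so errors do not accumulate — by an
   iterative global deformation built on `Nc` Gaussian radial basis
   functions of width `gamma`.
3. **Maps** (`displacement_map`, `diameter_map`, `transfer_diameter`).
   Displacement is the Euclidean distance between each reference vertex and
   its registered position. Diameter is measured per vertex by casting a ray
   along the inward normal to the first hit on the opposite wall. The
   reference diameter map is carried to each phase by the registration and
   compared with that phase's own diameter map; the difference is the
   diameter change (also expressed as a percentage of the reference
   diameter).
4. **Curves** (`phase_curves`). Mean and maximum displacement, mean
   diameter, and mean diameter change are aggregated per phase over the
   static ROI box.

## The registration model

Each G-RBF iteration `i` of `n_iterations = 30`:

* `k1` rises linearly from 1 to 1.5 and `k2` falls from 3 to 1.5;
* the number of deformation centres is `Nc = round(10 * k1)` (10 to 15),
  re-selected every iteration on the current warped surface by
  deterministic farthest-point sampling, because the schedule changes `Nc`;
* every source vertex is paired with its exact closest point on the target
  surface (point-to-triangle, not vertex-to-vertex — the two meshes have
  unrelated vertex counts);
* centre weights are fitted to the closest-point residuals by damped least
  squares (relative ridge `1e-6`; the kernel matrix is ill-conditioned for
  wide kernels), and the warp
  `x + sum_c w_c exp(-||x - c||^2 / gamma^2)` is applied.

The kernel width is `gamma = k2 * 2 * D_mean`, floored at twice the voxel
size, where `D_mean` is the mean distance from the source vertices to the
target surface. Three readings of which `D_mean` enters are implemented
(`gamma_mode`):

* `"schedule"` (default): `D_mean` measured once, before the first
  iteration. The coarse-to-fine progression then comes purely from the
  falling `k2`, and the kernels keep broad support to the end.
* `"adaptive"`: `D_mean` re-measured every iteration. This couples kernel
  support to the remaining misfit; once the misfit is below the
  inter-centre spacing, the 10-15 kernels cover only a small fraction of
  the surface and convergence stalls. On the straight-tube benchmark an
  8 mm translation is recovered to 7.5 mm with a final misfit of 0.24 mm
  under `"schedule"`, versus 6.0 mm and 1.04 mm under `"adaptive"` — which
  is why `"schedule"` is the default.
* `"inverse"`: the reciprocal reading `1 / (2 * D_mean * k2)`, selectable
  for completeness; it has units of 1/mm and is not recommended.

`nc_mode` similarly offers `"product"` (`Nc = round(10 * k1)`, default) and
`"power"` (`Nc = round(10 ^ k1)`).

**Rigid pre-alignment.** Before the G-RBF iterations, a translation-only
ICP stage repeatedly moves the source by the mean closest-point residual
(the Procrustes-optimal translation for the current correspondences) until
the step stalls below 0.01 mm. Closest-point flow only observes the
component of motion normal to the surface; without a global rigid stage the
local kernels make the surfaces coincide while the tangential part of a
bulk translation is silently dropped (a 2 mm translated sphere registers to
a mean displacement of 1.2 mm instead of 2.0 mm). With the stage, the same
fixture recovers 1.99 mm and a translated straight tube recovers an 8 mm
shift with 0.05 mm mean per-vertex error. The stage is switchable
(`prealign = "none"`). Note the inherent limit it cannot remove: a
translation of a (near-)cylindrical surface *along its own axis* is
invisible in the surface shape, for any shape-based method; displacement
estimates contain only the observable component of motion.

## Diameter by inward-normal ray casting

From every vertex a ray is cast along the negated outward normal; the
diameter is the distance to the first triangle intersection beyond a 0.5 mm
self-hit guard, invalid if there is no hit within 60 mm (rays escaping
through branch ostia or tube ends). Invalid vertices are excluded from ROI
aggregates rather than imputed — imputation would bias the means.

The measurement is sensitive to normal noise: a chord tilted by an angle
`a` within the cross-sectional plane has length `2r cos a`, so noisy
normals systematically *shorten* diameters. Two defaults control this:
the extraction pre-smoothing sigma of 0.8 voxel (at 0.5 voxel the
tetrahedral staircase leaves ~13 degrees of in-plane tilt and a -1.2 mm
bias on a 25.9 mm cylinder; at 0.8 voxel the tilt drops to ~6 degrees) and
three rounds of normal-only neighbourhood averaging (`smooth_normals`),
which denoise the direction field without moving a single vertex.

For diameter *change*, the reference diameter is transported by the
registration: each warped reference vertex is projected to its closest
point on the target surface and the target's own diameter map is
interpolated there barycentrically (the minimal smooth interpolation on a
triangulation). The alternative reading — re-measuring diameters on the
warped reference mesh itself — was not chosen because the warped mesh is a
deformation estimate, whereas the target-phase mesh is direct evidence of
that phase's geometry; registration error then only misplaces the sampling
location instead of corrupting the measurement.

## The ROI convention

The ROI is an axis-aligned box in world millimetres, defined once on the
reference phase and held static across phases. Membership is evaluated at
reference-phase positions for reference-indexed maps (displacement,
diameter change) — a vertex that translates out of the box at systole still
belongs to the ROI — and at each phase's own vertex positions for that
phase's diameter map. Anatomical landmarking (sinotubular junction, arch
midpoint) is deliberately manual: the box is user input.

## The synthetic phantom

`generate_phantom` builds a pulsating, translating "candy-cane" tube —
straight segment (50 mm) plus half-torus arch (radius 28 mm) — rasterized
at 1.6 mm isotropic voxels over 15 cardiac phases, emulating the geometry
of a 3D cine acquisition of the thoracic aorta. Its motion model is
deliberately simple so that ground truth stays analytic: the radius follows
`r(t) = r0 + amp * w(t)` and the whole tube translates rigidly by
`trans * w(t)`, with `w` a raised-cosine systolic upstroke to phase 5, an
exponential decay to a diastolic plateau, and a taper back toward zero — a
systolic peak followed by a diastolic plateau, the canonical shape of
aortic motion curves. Defaults: `r0 = 12.95` mm (a 25.9 mm vessel),
`amp = 0.7` mm (1.4 mm peak diameter change), `|trans| = 13` mm — the
magnitudes reported for the ascending aorta of healthy adults.

Two geometric choices matter for validation:

* the translation direction defaults to the normal of the centerline plane,
  so the bulk motion is observable from surface shape everywhere (see the
  pre-alignment note above);
* the centerline is tilted 8 and 6 degrees against the voxel lattice. A
  perfectly grid-aligned tube has every cross-sectional slice sampling the
  identical lattice offset, so rasterization quantization becomes a
  coherent per-phase diameter error of ~0.2 mm instead of averaging out —
  an artefact of the phantom, not of the pipeline, and one no real vessel
  exhibits. With the tilt, the pipeline recovers the 1.4 mm peak diameter
  change as 1.41 mm; without it, 1.03 mm.

What the phantom does *not* emulate: segmentation noise and topology errors,
branch vessels, wall tapering, elongation/shear (the motion is rigid +
uniform distension), bSSFP banding artefacts, and arrhythmia. Passing the
phantom suite therefore demonstrates the geometry pipeline is correct and
well-conditioned at the study's resolution; it does not certify performance
on imperfect real segmentations.

## Statistics

The reporting statistics mirror common practice for repeatability studies:
group curves as per-phase median and IQR (Q3 - Q1, linear-interpolation
quantiles); method agreement via Bland-Altman bias and 1.96-SD limits of
agreement plus Pearson correlation, gated by a Shapiro-Wilk normality check
on the differences (a warning, not a method switch); test-retest-rescan
repeatability as the maximum over phases of the across-scan range; segmentation
overlap as the Dice coefficient; and the area-derived diameter
`DA = 2 sqrt(A / pi)` for comparing against planimetric 2D measurements.
Differences in `agreement_stats(a, b)` are `a - b`.

## Numerical choices and degenerate inputs

* Masks are binarized at 0.5; a phase without foreground voxels is an
  error, multiple connected components keep the largest (with a warning).
* Marching tetrahedra interpolation clamps the edge parameter to
  `[1e-6, 1 - 1e-6]` so welded vertices never coincide exactly.
* Closest-point and ray queries are exact (Ericson's region decomposition,
  Moller-Trumbore) over a uniform spatial grid that only prunes candidates.
* The weight solve adds `damping * trace(K'K)/Nc` to the normal equations;
  a non-finite solve (degenerate gamma, duplicate centres) is an error.
* Farthest-point sampling seeds its start vertex from a small integer
  congruential map of `seed`, independent of R's RNG state, and breaks
  ties toward the lowest vertex index — registration is bit-reproducible.
* A failed phase inside `run_motion_analysis` is reported, flagged
  all-invalid, and the run continues; phase 0 maps are zero by
  construction.

## Problem sizes

The full-scale phantom produces meshes of roughly 20,000 vertices; a
complete 15-phase analysis (15 extractions, 14 registrations of 30
iterations each, 15 ray-cast diameter maps and the transfers) runs in about
90 seconds on one CPU core. The unit-test suite uses a reduced phantom
(8 mm radius, 6 phases) for speed; the acceptance suite exercises the
full-scale geometry.

## Known limitations

* Shape-based registration cannot observe tangential sliding; axial
  translation or elongation of a smooth tube is underestimated (see the
  pre-alignment note). This is inherent to registering segmentations rather
  than images.
* Diameter via the inward normal assumes a roughly tubular cross-section;
  at branch ostia and sharp bends the chord may not represent a diameter
  (such rays usually miss and are flagged invalid, but oblique hits near
  the arch's inner curvature can read long).
* The per-vertex diameter bias of the default extraction is about
  +0.5/-0.5 mm at 1.6 mm voxels depending on local curvature; diameter
  *changes* are more accurate because the bias largely cancels between
  phases.
* The ROI is a static axis-aligned box; strongly oblique anatomies may need
  a generous box or a resampled input orientation.
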