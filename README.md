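# aortamotion

Quantifies cardiac-cycle motion of the thoracic aorta from time-resolved 3D
binary segmentations (one mask per cardiac phase, NIfTI). For clinicians and
imaging scientists studying aortic biomechanics — distensibility, root
motion, test-retest repeatability — it turns a 4D mask series into
per-vertex surface maps of **displacement**, **diameter** and **diameter
change** for every phase, and summarises them as motion curves over a region
of interest such as the ascending aorta (AAo).

## Method

The first (end-diastolic) phase is the reference. Its surface S₀ is
extracted (marching tetrahedra on the Gaussian-smoothed mask, Taubin
smoothing) and registered independently to every phase t by iterative global
deformation with N_c Gaussian radial basis functions,

    x ↦ x + Σ_c w_c exp(−‖x − c‖² / γ²),

run for 30 iterations with schedules k₁: 1 → 1.5 and k₂: 3 → 1.5,
N_c = round(10·k₁) farthest-point-sampled centres per iteration, and kernel
width γ = k₂ · 2 · D_mean, where D_mean is the mean distance from source
vertices to the target surface. A rigid translation-only ICP stage absorbs
bulk motion first. Per reference vertex v:

* displacement_t(v) = ‖registered position − reference position‖₂,
* diameter_t(v) = length of the inward-normal chord to the opposite wall,
* diameter change_t(v) = target-phase diameter interpolated at the
  registered position − reference diameter (also as % of reference).

ROI curves report mean/max displacement, mean diameter and mean diameter
change per phase. Validation statistics: Dice coefficient, Bland-Altman bias
± 1.96·SD limits of agreement with a Shapiro-Wilk normality gate, Pearson r,
per-phase median (IQR) group curves, maximum test-retest-rescan variability,
and the area-derived diameter D_A = 2·√(Area/π).

A synthetic phantom (`generate_phantom`) provides analytic ground truth: a
pulsating, translating curved tube at 1.6 mm isotropic voxels and 15 phases,
by default a 25.9 mm vessel with 1.4 mm peak diameter change and 13 mm peak
bulk translation.

## Worked example

```r
library(aortamotion)

spec    <- phantom_spec()              # 25.9 mm vessel, 15 phases, 1.6 mm voxels
phantom <- generate_phantom(spec)      # masks + analytic ground truth
roi     <- phantom_roi(spec)           # box over the straight segment
result  <- run_motion_analysis(phantom$series, roi)
subset(as.data.frame(result$curves), phase %in% c(0, 3, 5, 8),
       c(phase, mean_displacement_mm, mean_diameter_mm, mean_diameter_change_mm))
```

```
  phase mean_displacement_mm mean_diameter_mm mean_diameter_change_mm
1     0                 0.00            26.39                    0.00
4     3                 8.47            27.22                    0.91
6     5                12.95            27.71                    1.41
9     8                 6.75            27.09                    0.74
```

Phase 0 is the reference (zero by construction). At the systolic peak
(phase 5) the pipeline recovers a mean displacement of 12.95 mm against the
phantom's true 13.01 mm, and a mean diameter change of 1.41 mm against the
true 1.4 mm (2·amp); the reference mean diameter reads 26.39 mm for the
25.9 mm tube, i.e. within a third of a voxel. Real data go through the same
call with `read_mask_series("masks4d.nii.gz")` and an ROI box in scanner
millimetres; per-vertex maps live in `result$maps` and export to PLY/CSV.

A command-line wrapper with `analyze`, `phantom`, `compare` and `dice`
subcommands is installed at `inst/scripts/aortamotion.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/aortamotion.R", package="aortamotion"))')" \
  analyze --masks masks4d.nii.gz --roi 20,40,10,60,80,60 --out results/
```

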