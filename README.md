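# tsmorph

Muscle-tendon morphometry and gait mechanics for the triceps surae /
Achilles tendon complex, with a fully verifiable synthetic-data path.

## The problem

Plantarflexor output during walking depends on the interaction of the
triceps surae muscles — medial and lateral gastrocnemius (MG, LG) and
the posterior/anterior compartments of the soleus (PS, AS) — with the
Achilles tendon. Studying how muscle size, tendon size, and joint
function relate across age groups requires a chain of measurements
drawn from quite different instruments: muscle volumes and tendon
cross-sectional areas (CSA) from segmented 3-D images, the tendon
moment arm from combined motion capture + ultrasound, and peak ankle
torques from instrumented-treadmill inverse dynamics, tied together by
rank-based group comparisons and allometric scaling regressions.

`tsmorph` implements that whole chain for researchers in
musculoskeletal biomechanics: each stage is a small set of documented R
functions, and a synthetic-data generator produces label-map phantoms,
range-of-motion trials, gait trials, and two-group cohorts with known
ground truth, so every stage — and the pipeline end to end — can be
validated without access to subject data.

## Methods at the core

- **Volumetry**: volume(label) = voxel count × voxel volume; relative
  volume = muscle/total × 100%; normalized volume = volume/(height × mass)
  in cm³/(kg·m).
- **Tendon geometry**: per-slice CSA in the axial plane; free-tendon
  length = Σ‖c_{i+1} − c_i‖ over slice centroids between the calcaneus
  and soleus muscle-tendon-junction landmarks; representative CSA at
  50% of the centroid-path length; 101-point CSA profile on normalized
  length.
- **Moment arm**: least-squares rigid poses (SVD/Kabsch) → finite
  helical axes between pose pairs spanning ≥5° → rotation-weighted
  functional axis; tendon line of action by total least squares through
  ultrasound edge-pair midpoints; moment arm as the skew-line distance
  |(p₁−p₂)·(d₁×d₂)|/‖d₁×d₂‖, evaluated at 0° by a quadratic fit in
  ankle angle.
- **Gait kinetics**: 20 N / 50 ms gait events; sagittal-plane
  Newton-Euler on the foot (plantarflexion positive), 101-point cycle
  normalization, peaks averaged across ≥10 strides; tendon force =
  torque / moment arm.
- **Statistics**: exact Mann-Whitney U (full enumeration for pooled
  n ≤ 25, tie-free), Holm step-down over the four per-muscle tests —
  uncapped by default so adjusted p > 1 stays visible — and
  closed-form OLS with slope t-tests.

## Worked example

```r
library(tsmorph)

# a labeled limb phantom at the acquisition voxel size (0.72 x 0.72 x 2 mm)
vol <- generate_label_volume(c(PS = 391.4, AS = 83.8, MG = 291.6, LG = 175.1),
                             tendon = tendon_spec(61.35, 26))
morpho <- compute_muscle_volumes(vol, height_m = 1.78, mass_kg = 74.87)
morpho
#> muscle_morphometry: total 941.9 cm^3
#>    volume_cm3 relative_pct
#> PS      391.5        41.56
#> AS       83.8         8.90
#> MG      291.6        30.96
#> LG      175.0        18.58

tendon_geometry(vol)
#> tendon_geometry: 26 slices, length 50 mm, volume 3.18 cm^3,
#>                  mid-length CSA 61.2 mm^2

# moment arm from a synthetic range-of-motion trial (0.5 mm marker noise)
rom <- generate_rom_trial(axis = list(point = c(30, 40, 60),
                                      direction = c(0.97, 0.17, 0.17)),
                          quad_coeffs = c(46.64, -0.1, -0.01),
                          marker_noise_sd = 0.5, edge_noise_sd = 0.3, seed = 1)
analyze_rom_trial(rom)$curve
#> moment_arm_curve: 91 frames, moment arm at 0 deg = 46.54 mm

# treadmill gait round trip: a 114.23 Nm peak-torque waveform is recovered
gait <- generate_gait_trial(114.23, n_strides = 12, seed = 1)
jk <- ankle_inverse_dynamics(gait)
jk
#> joint_kinetics: 11 cycles, mean peak 114 +/- 0 Nm
estimate_tendon_force(jk$mean_peak_nm, 46.64)
#> [1] 2445.18
```

The measured muscle volumes sit within 0.1% of the analytic phantom
volumes; the moment arm at 0° is recovered within ~0.2 mm of the
generating quadratic's constant under bench-level noise (exactly, at
zero noise); and the inverse-dynamics round trip returns the generated
peak torque to ~0.2%.

A full study emulation — a 14 young + 7 older cohort, per-subject
phantoms and trials, measurement of everything back through the
pipeline, and the three cohort report tables — is in the numbered
scripts under `analysis/`:

```sh
Rscript analysis/01_phantom_validation.R
Rscript analysis/02_moment_arm_validation.R
Rscript analysis/03_gait_validation.R
Rscript analysis/04_cohort_pipeline.R      # writes results/pipeline/
Rscript analysis/05_replication_study.R
```

`analysis/04_cohort_pipeline.R` prints, per group, the measured
volumes, tendon CSA, moment arm, peak torque, and tendon force, then
the key cohort contrasts (e.g. tendon CSA ~ total volume: young
R² ≈ 0.9, older R² ≈ 0.03 — the coupling present in the young group
and absent in the older one). `analysis/05_replication_study.R` repeats
the cohort analysis over 200 seeds and reports detection rates and the
empirical power of the normalized-volume comparison.

## Package layout

- `R/` — generators (`generate_cohort`, `generate_label_volume`,
  `generate_rom_trial`, `generate_gait_trial`), measurement stages
  (`compute_muscle_volumes`, `tendon_geometry`, `analyze_rom_trial`,
  `ankle_inverse_dynamics`), statistics (`mann_whitney`,
  `holm_bonferroni`, `linear_regression`, `build_tables`), and the
  orchestrated `run_pipeline`.
- `analysis/` — the numbered study scripts (thin drivers; all
  computation lives in the package).
- `vignettes/tsmorph-methods.Rmd` — models, assumptions, parameter
  provenance, and design decisions.
- `tests/testthat/` — unit, property, and end-to-end accuracy tests
  against analytic and enumerated oracles.
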