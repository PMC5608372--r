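# embryOx

Oxygen transport modelling and migration-kinetics quantification for
*Drosophila* embryos developing in microfluidic oxygen gradients.

## The problem

Developing fly embryos are strikingly oxygen-sensitive: pole-cell migration
and germband shortening (tail retraction) slow down under moderate hypoxia,
and tail retraction arrests below a critical oxygen level, resuming when
normoxia returns. A microfluidic device with two gas microchannels imposes a
controlled oxygen field (plateaus of 3% and 20% O₂ with a sharp gradient
across the wall between them), so embryos can be placed parallel to the
channels (whole body at one oxygen level) or perpendicular, spanning the
gradient. Because the same developmental clock — the passage interval of the
10th and 11th *engrailed* stripes past the posterior tip — can be read in
both geometries, the otherwise inaccessible oxygen permeability of the
embryonic layers becomes estimable.

`embryOx` is for quantitative developmental biologists and tissue-scale
modellers who want that whole chain as tested, reusable code:

* **Stern–Volmer sensor calibration**: `fitSternVolmer()`,
  `intensityToOxygen()`, `rollingAverage()`.
* **Device oxygen field**: `deviceOxygenAt()`, `externalFieldForPlacement()`
  — a logistic profile calibrated to the printed plateaus and peak gradients
  (0.028 %/µm at the membrane, 0.023 %/µm at 180 µm).
* **3D finite-volume embryo model**: `voxelize()`, `solveSteadyState()`,
  `solveTransient()`, `regionAverage()` — for every cubic element,
  Σₙ (C_iₙ − C_i)·η·S = R·V with η = D/l inside and η = E (membrane
  permeability) on the boundary, zero-order consumption with dead-core
  (anoxic region) handling, implicit-Euler transients.
* **Permeability inference**: `estimatePermeability()`,
  `findEquivalentUniformOxygen()`, `sensitivityAnalysis()` — fits E so the
  simulated posterior-75% mean oxygen of each wall-spanning placement matches
  the tissue oxygen implied by its measured migration time.
* **Dose–response**: `fitDoseResponse()`, `evalDoseResponse()`,
  `invertDoseResponse()` — the one-term exponential
  [O₂](t) = a + b·exp[−c(t + d)] with right-censored (no-migration)
  observations entering at the 500-min watch time.
* **Kinetics quantifiers**: `migrationTime1090()`, `meanVelocity()`,
  `stripeMigrationTime()`.
* **Synthetic data**: `genSensorMap()`, `genTrajectory()`,
  `genMigrationDataset()`, `genStripePassages()` — every pipeline input with
  known ground truth, bit-reproducible under a seed.
* **Pipeline**: `validateConfig()`, `runPipeline()` — YAML/list config with
  published defaults, one JSON summary, byte-identical reruns.

## Worked example

```r
library(embryOx)

## 1. Calibrate the oxygen sensor at 0 / 10 / 21 % O2
cal <- fitSternVolmer(c(0, 10, 21), c(1000, 667, 488))
cal
#> Stern-Volmer calibration: I0 = 1000  Ksv = 0.04995433 per % O2

## 2. The published stripe-migration dose-response and its arrest threshold
ref <- referenceDoseResponse()
evalDoseResponse(ref, 1e9)
#> [1] 4.93

## 3. Refit the curve from synthetic noisy migration-time data
set.seed(1)
ds <- genMigrationDataset(50, ref, c(5.5, 20), noiseSd = 0.5)
fitDoseResponse(ds)
#> Dose-response curve: [O2] = 4.347 + 16.74 * exp[- 0.0272 (t + 0 )]  (% O2, t in min)
#>   residual sum of squares: 9.795

## 4. Voxelize the default embryo and estimate the membrane permeability
grid <- voxelize(embryoGeometry())     # 500 x 180 x 180 um, 10 um voxels
grid
#> Voxel grid: 8544 elements, 23952 interior faces, 3360 boundary faces (voxel edge 10 um)
estimatePermeability(grid = grid)
#> Permeability estimate: E = 1.293e-05 m/s ( 0.001293 cm/s )
#>   objective: 0.006116 ; residuals (% O2): -0.0542,  0.0564
```

Reading the output: the fitted asymptote (4.35% here; 4.93% in the reference
curve — at n = 50 the extrapolated asymptote scatters with sd ≈ 0.45) is the
oxygen level below which tail retraction arrests. The permeability estimate,
1.3 × 10⁻³ cm/s, is the membrane conductance at which the simulated interior
oxygen of the two wall-spanning placements (mid-AP and mid-PA) matches the
tissue oxygen implied by their measured 60- and 83-min migration times; the
per-constraint residuals show both equivalences are met within ±0.06% O₂ at
a single E.

The measured pole-cell endpoint statistics give the headline slowdown
directly: `100 * 112.6 / 47.5` = 237% (hypoxic vs normoxic mean migration
time).

## Vignette

`vignettes/oxygen-transport-modelling.Rmd` documents the model equations and
assumptions, the dead-core treatment, the identifiability of the
dose-response coefficients, the reconstruction choices behind the device
profile and the matching statistic, and the known limitations.
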