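# cardioflow

Quantitative cardiac MRI in two parts:

1. **LV flow-component separation (4D flow MRI).** The left-ventricular
   end-diastolic blood pool is seeded with one massless particle per voxel
   and every particle is traced forward and backward through the
   time-resolved, three-directional velocity field to the adjacent
   end-systoles. Where a pathline sits relative to the end-systolic
   segmentations partitions the end-diastolic volume (EDV) into **direct
   flow** (entered during diastole, ejected the same cycle), **retained
   inflow**, **delayed ejection flow** and **residual volume**, with
   kinetic energy KE = ½·ρ·V·v² (ρ = 1060 kg/m³) accounted per component
   and the inflow split into early (E-wave) and late (A-wave) fractions at
   the diastasis.

2. **Myocardial blood flow from FAIR ASL.** Control/tag image series are
   quantified with the single-TI Buxton model,
   MBF = λ·(C − T)/(2·M0·TI·e^(−TI/T1))·60000 ml/g/min (TI = R-R interval,
   T1 = 1650 ms, λ = 1), after polar resampling and angular filtering of
   the myocardial ring (global 2π / regional π/3 × 6 / septal 2π/3 × 3
   configurations), and the temporal noise of the serial estimates is
   decomposed into physiological (motion-driven) and thermal components in
   quadrature.

No patient data accompany these methods, so the package ships synthetic
generators with oracle-computable ground truth — a uniform duct, a
solid-body rotation, a contracting half-ellipsoid ventricle (EDV 179 mL,
EF 42%, 61 bpm, 3 mm voxels, VENC 100 cm/s), and a FAIR-ASL forward model
whose noise-free case the quantifier inverts exactly. The whole pipeline is
validated against these phantoms. It is intended for researchers building
or testing flow-component and cardiac-ASL analysis code, not for clinical
use.

## Worked example

```r
library(cardioflow)

## 4D flow: phantom -> pathlines -> components
ph  <- make_lv_phantom(phantom_params())      # field + geometry + truth
fit <- lv_flow(ph$field, ph$geometry)
fit
#> LV flow-component analysis
#>   EDV 179.0 mL; inflow 77.1 mL; ejected 77.4 mL
#>   direct              63.2 mL (35.3% of EDV); KE at ED 0.00 uJ/mL
#>   retained_inflow     13.9 mL ( 7.8% of EDV); KE at ED 0.00 uJ/mL
#>   delayed_ejection    14.1 mL ( 7.9% of EDV); KE at ED 0.00 uJ/mL
#>   residual            87.8 mL (49.0% of EDV); KE at ED 0.00 uJ/mL
#>   direct/inflow 82.0% (early 47.1% + late 34.8%)
#>   QC: 0/6630 invalid (0.00%) -> PASS
```

The 6630 pathlines carry 27 mm³ each, so the four components sum exactly to
the 179.0 mL EDV; inflow (77.1 mL) and ejected volume (77.4 mL) both
recover the prescribed stroke volume EF·EDV = 75.2 mL to within 3%, and no
pathline leaves the blood pool anywhere but the two orifices (QC PASS at
zero invalid). Kinetic energy at the ED instant is zero because the phantom
is exactly quiescent at the R wave; `plot(fit)` shows the KE of each
component over the full cycle.

```r
## FAIR ASL: simulate a reference-protocol series and quantify it
s <- simulate_asl_series(asl_protocol(),       # 96 lines, 307 ms window
                         asl_truth(mbf_true = 1.20, seed = 7))
mbf_segments(s)
#> MBF fit: global 1.353 ml/g/min (6 pairs)
#>   regional (6 seg): 1.032 2.738 2.696 1.911 0.243 -0.500
#>   septal   (3 seg): 2.717 2.303 1.077
#>   noise: PN 0.1755, TN 0.0459 ml/g/min
```

At the default calibrated motion level the six-pair global estimate sits
near the true 1.20 ml/g/min while individual π/3 segments are visibly
noisy — the expected behaviour of single-slice cardiac ASL, where
physiological noise (~0.18 ml/g/min here) dominates thermal noise (~0.05).
With `asl_truth(motion_amplitude = 0, thermal_sd = 0)` every segment
returns 1.20 exactly. Re-running with
`asl_protocol(sense_factor = 2)` (153 ms window) roughly halves the
motion-induced spread.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cardioflow.R` (subcommands `simulate-flow`, `trace`,
`components`, `simulate-asl`, `quantify-asl`, `timing`, `report`).

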