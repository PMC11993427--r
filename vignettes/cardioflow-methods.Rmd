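---
title: "Methods: LV flow components from 4D flow MRI and FAIR-ASL perfusion"
author: "cardioflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV flow components from 4D flow MRI and FAIR-ASL perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflow)
```

cardioflow implements two quantitative cardiac-MRI analyses as tested,
reusable estimators: pathline-based separation of the left-ventricular (LV)
end-diastolic blood pool into four functional flow components with kinetic
energy accounting, and Buxton-model myocardial blood-flow (MBF)
quantification from FAIR arterial spin labelling (ASL) with a
physiological/thermal noise decomposition. Because no patient scans
accompany these methods, both analyses are driven by synthetic generators
whose ground truth is known by construction; this vignette describes the
models, the generators, the numerical choices, and exactly what passing
tests do and do not establish about real data.

## 1. Pathline separation of LV flow components

### The procedure

A time-resolved, three-directional velocity field (4D flow MRI) is sampled
on an isotropic voxel grid over one cardiac cycle. The analysis seeds one
massless particle at the centre of every voxel of the end-diastolic (ED)
blood-pool segmentation, so that each pathline represents exactly one voxel
volume of blood and the seed set represents the full end-diastolic volume
(EDV). Every particle is traced backward in time to the preceding
end systole (ES) and forward to the following ES. Its position relative to
the ES segmentations then assigns one of four components:

| at preceding ES | at following ES | component |
|---|---|---|
| outside | outside | direct flow |
| outside | inside  | retained inflow |
| inside  | outside | delayed ejection flow |
| inside  | inside  | residual volume |

Volumes are attached at seeding and never rescaled, so the four components
partition the EDV by construction, inflow = direct + retained inflow, and
ejected = direct + delayed ejection. Kinetic energy per pathline and frame
is $KE = \tfrac12\,\rho\,V_{\mathrm{pathline}}\,v_{\mathrm{pathline}}^2$
with blood density $\rho = 1060$ kg/m³, reported in µJ and, per component,
normalised by the component volume (µJ/mL).

Diastole is split at mid-diastole, defined as the diastolic frame interval
with the fewest pathline crossings of the mitral valve plane (the
diastasis), ties breaking toward the earlier frame. Direct-flow and
retained-inflow pathlines are labelled *early* or *late* by whether their
mitral-plane crossing precedes that frame, so the early and late
direct-flow fractions of total inflow add up to the overall direct/inflow
ratio. The "fewest plane crossings" reading of the mid-diastole rule is one
of two possible interpretations (the other being the length of the
intersection line of pool and plane); the crossing count is implemented
because it is the only reading that yields a unique, computable frame for
any pathline set. Whether retained inflow uses the same mid-diastole frame
as direct flow is not separately specified anywhere; the same frame is
used for both.

### Integration and interpolation

Pathlines are integrated with fixed-step fourth-order Runge–Kutta, 4
substeps per frame interval by default, with trilinear spatial and linear
temporal velocity interpolation. No integration scheme is mandated by the
underlying method; RK4 with these settings is standard for cine
phase-contrast pathlines, is exact on constant fields, and reproduces a
20-substep reference integration on the LV phantom to well under half a
voxel at every endpoint, with identical component labels when the substep
count is doubled. Velocities outside the blood pool are looked up as-is
(the generators zero them); there is no wall-repulsion correction, because
quality control — not masking — is the error-handling mechanism.

### Quality control

A pathline may leave the blood pool only through the mitral or aortic
orifice. Exits through wall-labelled surface faces (including the apex)
mark the pathline `exited_wall`; the dataset report gives the invalid
fraction and fails above a configurable threshold (default 5%; the
underlying method reports only that all its datasets passed, so the
threshold is this package's choice and is exposed in `trace_config()`).
Two numerical details matter:

* Exit events are detected against a **one-voxel dilation** of the pool
  mask. A voxelised surface is jagged at the scale of half a voxel, and a
  particle legitimately moving along the wall would otherwise be flagged
  whenever its rounded position grazes the staircase. The consequence is a
  sensitivity floor: wall excursions shallower than one voxel are below
  the segmentation's resolution and are not flagged.
* Classification itself uses the strict ES masks with voxel-centre
  containment, matching the definition of the components.

### The phantoms and their ground truth

Three generators stand in for patient data.

**Duct phantom** (`make_duct_phantom()`): a box ventricle in a spatially
and temporally uniform velocity field along +x, inlet face labelled mitral,
outlet aortic. The field is uniform over the whole grid — a constant field
is represented exactly by trilinear interpolation — so pathlines obey
$x(t) = x_0 + vt$ to machine precision and component labels have a closed
form in the seed coordinate.

**Rotation phantom** (`make_rotation_phantom()`): solid-body rotation about
the chamber axis of a cylindrical pool. The field is linear in position and
extends (speed-clamped) past the wall, so interpolation is again exact:
every pathline is a circle of constant radius and speed, and every label is
residual. The phantom's ES "segmentation" carries a 0.75-voxel radial
margin so that exact orbits always round inside it — without the margin,
the voxel-centre containment test itself (not the tracing) misreads rim
orbits against the jagged mask edge. This is documented as a segmentation
convention of the generator, not a tracing tolerance.

**LV phantom** (`make_lv_phantom()`): a half-ellipsoidal chamber (apex
down) whose cavity volume follows a prescribed periodic cycle: a
raised-cosine systolic ejection to $ESV = EDV(1-EF)$, then an E wave, a
zero-flow diastasis gap, and an A wave ending at the R wave, with the
inflow volume split `e_a_ratio : 1` between the waves. Defaults are the
study conditions: EDV 179 mL, EF 0.42, heart rate 61 bpm, 30 frames, 3 mm
voxels, VENC 100 cm/s. The E/A ratio defaults to 1.5, a typical
early-dominant filling pattern; the raised-cosine pulses with a true
zero-flow diastasis make the mid-diastole rule well defined.

The interior field is assembled from closed forms:

* a quasi-1D core — axial velocity from the cross-sectional flux balance
  with a linear radial profile — which is exactly divergence-free and
  exactly wall-conforming for the axisymmetric chamber;
* near the base, a blend of the axial flow into a truncated-Gaussian jet
  confined to the active orifice disk (mitral while filling, aortic while
  ejecting), with jet weights normalised slice-wise on the grid so the
  base-plane flux equals the prescribed $dV/dt$ by construction;
* the in-plane "funnel" flow restoring continuity of the jet blend: the
  Neumann Green's-function solution in each circular cross-section (radial
  flow about the orifice axis, its point image about the circle-inverse
  point, and the uniform compensation about the chamber axis). Without
  this term the interpolated field is divergent near the base and
  Lagrangian transport under-ejects by ~20%;
* a short tapered continuation of the active jet above the base plane (the
  vessel/atrial stub), so particles cross the base at full jet speed and
  park cleanly outside instead of piling against zero-filled voxels;
* a "wall halo": voxels between the instantaneous cavity and the ED cavity
  carry the wall-clamped field value, so near-wall interpolation does not
  make particles lag the moving wall. Voxels outside the ED pool are zero.

The ED radius is calibrated so the voxelised EDV matches the requested
volume to within one voxel (the chamber axis gets a seed-dependent
sub-voxel offset so the voxel count steps singly during calibration, which
also makes different seeds give distinct voxelisations).

**Ground truth** is computed by a converged reference integration — RK4 at
20 substeps per frame interval, a step at which halving changes no label —
of the *same grid field*, not of the underlying closed forms. The generated
dataset *is* the sampled field; defining truth on the closed forms instead
would conflate spatial-discretisation error (a property of the dataset)
with integration error (a property of the tracer under test). For the duct
and rotation phantoms the two coincide exactly, because their fields are
trilinear-exact.

### What the phantom does and does not establish

The phantom guarantees the properties the analysis assumes — a closed blood
pool with exactly two orifices, a known volume curve, massless transport —
and deliberately omits trabeculae, valve leaflets, turbulence, velocity
noise and aliasing (VENC wrap is out of scope). Passing tests therefore
demonstrate correct seeding, integration, QC, classification, conservation
and energy accounting on clean fields; they do not demonstrate robustness
to measurement noise or segmentation error in patient data.

One conservation property has a measured floor worth stating plainly: on
the default phantom the inflow and ejected volumes each match the stroke
volume to better than 3%, and match *each other* to 0.22 mL (8 voxels,
0.3% of stroke volume) — but not to one voxel. The residual asymmetry is
deterministic (identical across seeds and substep counts) and structural:
with a biphasic E/A diastole the diastolic Lagrangian map is not the
mirrored time-reverse of the systolic map, so the two shallow boundary-layer
populations at the orifices cannot cancel exactly; only a time-symmetric
single-wave cycle would make them do so, and the diastasis/E/A design is a
requirement, not an option. The corresponding acceptance assertion is kept
at the one-voxel figure and is expected to stay red.

A related idealisation: the default phantom is exactly quiescent at the ED
frame (the A wave ends with zero rate at the R wave), so every component's
kinetic energy at ED is exactly zero. KE comparisons on the phantom are
therefore made over the cycle, not at the ED instant.

## 2. FAIR-ASL myocardial blood flow

### Quantification

A FAIR series consists of a baseline image (the equilibrium-magnetisation
surrogate M0), thermal-noise images, and six control/tag pairs acquired in
separate breath-holds on a mid-ventricular short-axis slice. MBF follows
the single-TI Buxton model,

$$\mathrm{MBF} = \lambda\,\frac{C - T}{2\,M_0\,TI\,e^{-TI/T_1}}\times 60000
\quad[\mathrm{ml/g/min}],$$

with the control and tagged myocardial signals $C$, $T$, the inversion
delay $TI$ equal to the R-R interval, blood $T_1 = 1650$ ms, and a
blood–tissue partition coefficient $\lambda = 1$ ml/g; 60000 converts per-ms
to per-min. (The printed form of this equation in the source literature is
typographically garbled; the implementation uses the standard single-TI
bracketing above, which is the dimensionally consistent reading of the
cited model.) The myocardium is resampled to polar coordinates (60 angular
bins of 6°), an angular boxcar of configurable width is applied per pair
(wrapping; width 2π reduces to the global mean; even bin counts take the
extra bin on the earlier side), and segment values average the filtered
bins within each segment and then the pairs — filtering before averaging,
since the order is not specified anywhere. Three configurations are
reported: global (1 segment, 2π filter), regional (6 segments, π/3),
septal (3 segments over the septal half of the ring, 2π/3; which half is
septal is a configuration value). Negative MBF values are returned as-is
with a flag, never clipped.

### Noise decomposition

With per-pair global MBF values $m_1,\dots,m_6$: total temporal noise
$\sigma_t = \mathrm{sd}(m)/\sqrt{n}$; thermal noise TN propagates the
noise-image standard deviation through the quantification equation for the
whole-ring mean ($\mathrm{sd}(\bar C - \bar T) = \sigma_{px}\sqrt{2/N}$)
and divides by $\sqrt{n}$; physiological noise is the quadrature remainder
$PN = \sqrt{\max(0, \sigma_t^2 - TN^2)}$, clamped at zero. The cited
decomposition is not reprinted in the source; these formulas are this
package's contract and are validated against hand-computed cases and a
Monte-Carlo thermal floor.

### The ASL forward model

`simulate_asl_series()` inverts the quantification exactly in the
noise-free case: the tagged image differs from the control by
$2 M_0 TI e^{-TI/T_1}\,\mathrm{MBF}/60000$ on the myocardial annulus, with
$M_0$ the ring mean of the model's own baseline. Two noise mechanisms are
added:

* **Physiological (motion)**: each acquired image is rigidly displaced
  in-plane by an independent Gaussian draw whose standard deviation is
  `motion_amplitude × acquisition_window / 307 ms` — motion during a longer
  readout leaves larger control/tag inconsistencies, which is the stated
  mechanism of physiological noise in cardiac ASL. A perfectly concentric
  ring has *zero* linear response to translation, so the scene carries
  fixed, deterministic anatomical texture (papillary muscles, septal
  brightening, epicardial fat, a lung/liver interface, 2-mm edge widths)
  that breaks the rotational symmetry the way real short-axis anatomy
  does. `motion_amplitude` is an *effective* between-image displacement
  scale — it lumps every motion-induced reconstruction inconsistency into
  one rigid shift — and its default, 1.0 mm, is calibrated so the
  reference protocol's PN is ≈ 0.20 ml/g/min, the scale reported for
  resting cardiac ASL.
* **Thermal**: additive Gaussian noise of standard deviation
  `thermal_sd × sqrt(sense_factor)` on every image (the √R g-factor-style
  penalty of parallel imaging); the noise images carry thermal noise only.

Acceleration is modelled *only* as fewer acquired lines (a shorter window:
`floor(matrix_lines / sense_factor × tr)`, 307 ms at R = 1 and 153 ms at
R = 2, plus a lumped 133 ms fat-saturation/ramp overhead giving 440/286 ms
total windows — the overhead is a single configuration value because its
published decomposition is incomplete) plus the thermal inflation; no
aliasing or unwrapping is simulated. Under this contract PN scales with the
window, so the simulated reference→accelerated reduction is ~65% with the
thermal floor included; the direction of the effect (accelerated PN lower
in ≥ 95% of equal-seed paired replicates) is the validated claim, not the
percentage.

## 3. Problem sizes and determinism

The validation suite runs the default LV phantom (6630 pathlines × 30
frames, ~8 s to trace at production settings, ~40 s for the 20-substep
reference), two analytic phantoms, and Monte-Carlo ASL batches of 40–200
replicates (~70 ms per simulate-and-quantify cycle); these sizes were
chosen so each property is measured with comfortable margin on a single
CPU. Every stochastic component is seeded: phantoms are bit-identical under
a fixed seed, ASL series restore the caller's RNG state, and the
acceptance script derives all of its seeds from its `--seed` argument.

## 4. Known limitations

* The LV phantom's flow topology is simple (no vortex ring, no atrial
  chamber); the direct-flow fraction it produces (~80% of inflow) is
  higher than in dilated-cardiomyopathy patients (~46%), so component
  *proportions* are not comparable to patient cohorts — only the
  machinery that measures them is validated.
* Sub-voxel wall leaks are below the QC detection floor by design.
* The ASL motion model is rigid and in-plane; through-plane motion,
  banding, and gating jitter are out of scope.
* The mid-diastole rule presumes a detectable diastasis; tachycardic
  E/A-fused filling would make the minimum ill-defined (the earliest
  minimum is then returned).
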