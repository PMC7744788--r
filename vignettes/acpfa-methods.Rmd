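---
title: "Modelling AC pulsed-field cardiac ablation with acpfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling AC pulsed-field cardiac ablation with acpfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpfa)
```

## What the package models

Pulsed-field ablation (PFA) kills myocardium by irreversible
electroporation (IRE): brief high-voltage pulses raise the local electric
field above a lethal threshold (about 400 V/cm for muscle) without relying
on heat. `acpfa` models a particular flavour of PFA in which energy is
delivered as *AC bursts*: 100 µs trains of bipolar 100 kHz square
oscillations ("ten oscillations per burst"), ECG-gated so that each burst
lands 50–75 ms after an R wave, inside the ventricular refractory period.
Typical protocol settings are 900 V for 60 bursts in the atrium and
1500 V for 120 bursts across the interventricular septum, with the burst
rate set by the native sinus rhythm (an 800 ms inter-burst interval at
75 bpm).

The package covers the full computational chain around that protocol:

1. **protocol** — burst waveform synthesis, R-peak detection, gated
   scheduling;
2. **scenario** — voxelized geometries for three catheter settings
   (pulmonary-vein ostium, flat atrial wall, trans-septal electrode pair)
   with material properties;
3. **electrics** — a quasi-static conduction solve giving the field map,
   current density and delivered current;
4. **thermal** — the temperature transient of one gated burst with Joule
   heating and convective blood cooling;
5. **lesion** — IRE-threshold extent metrics, untreated-gap and
   misalignment sensitivity, exponential decay fitting;
6. **study_metrics** — segmentation volumetrics and the accompanying
   electrophysiology statistics;
7. **synthetic_data** — seed-deterministic generators that make every
   stage testable without external data.

## The burst model and its duty cycle

A burst is parameterized by `BurstSpec(amplitudeVolts, durationUs,
internalFreqKhz, duty, nBursts)`. The number of oscillations,
`durationUs * internalFreqKhz / 1000`, must be a whole number; the default
100 µs at 100 kHz gives ten.

"50% duty cycle" admits two readings: an on-time fraction, or merely a
symmetric bipolar square. We provide both in one parameterization: each
oscillation period is laid out as `+V` for `duty/2` of the period, off,
`-V` for `duty/2`, off. With `duty = 1` this degenerates to the continuous
bipolar square; with the default `duty = 0.5` the voltage is applied half
the time. This choice preserves the oscillation count and charge symmetry
while making `duty` a true power fraction: `dutyPowerFactor()` — the mean
of `(v(t)/V)^2` used to scale the Joule source — equals `duty` exactly.
Waveforms are sampled at cell-centred times, which makes the discrete
time-integral exactly zero (charge balance).

```{r burst}
spec <- BurstSpec(900)
w <- synthesizeBurst(spec, sampleRateHz = 1e7)
c(samples = nrow(w), integral = sum(w$voltage_v), duty = dutyPowerFactor(spec))
```

Gating mirrors a threshold comparator on lead III: one peak per
over-threshold excursion, excursions closer than 50 ms merged (a noise dip
inside a QRS must not split it), and a 200 ms refractory lockout. The
lockout is our choice — comfortably below the minimum physiological R-R at
sinus rates — as is the hard rejection of delays outside [50, 75] ms,
which we treat as a safety window rather than a soft warning.

## Scenario geometries and materials

Grids are isotropic voxel arrays (cell-centred coordinates, mm, 0-based
half-open extents) labelling blood, myocardium, line/neutral electrode and
insulator voxels. Electrodes are Dirichlet-voltage voxel groups (perfect
conductors); this is the grid-level equivalent of metal electrodes on an
insulating shaft. Odd-numbered loop electrodes go to the line pole and
even ones to the neutral pole, so adjacent ring electrodes always form
anode–cathode pairs.

* `buildPVOstium()` — a 12–14 mm blood lumen through a myocardial wall,
  ten 1 mm electrode segments on the lumen rim.
* `buildAtrialWall()` — a flat trabecula-free slab (default 5.85 mm, a
  typical atrial mean) under a blood pool, with a 20 mm ten-electrode
  loop resting on the endocardial face.
* `buildSeptal()` — a 15 mm septal slab with blood on both faces, a 4 mm
  line tip on one side and a 2 mm neutral tip on the other, with optional
  lateral offset and tilt. Tips are modelled as capsules whose lowest
  point touches the tissue face, so a tilted electrode can never
  penetrate the wall.

Default materials are literature-range values (myocardium
σ = 0.381 S/m, k = 0.56 W/m/K, ρ = 1081 kg/m³, c_p = 3686 J/kg/K; blood
0.70 S/m, 0.52 W/m/K, 1050 kg/m³, 3617 J/kg/K; platinum electrodes, nylon
insulator; baseline 37 °C). Every value is overridable through
`defaultMaterialTable()` or the `materials` config block, and all
downstream acceptance properties are written to be robust to these
choices.

## The conduction solve

`solvePotential()` solves ∇·(σ∇φ) = 0 with φ fixed on the electrodes and
zero normal flux on the outer boundary, using a 7-point finite-volume
stencil with harmonic-mean face conductivities (the flux-continuous choice
across material interfaces) and a Jacobi-preconditioned conjugate-gradient
iteration to a relative residual of 1e-8. The solve is DC-equivalent at
the burst plateau voltage: no 100 kHz dispersion or skin effect, matching
the use of static conductivities for per-burst field maps. The far-field
condition is our choice (the source model does not state one); generous
domain padding mitigates it. Fields are recovered by central differences
(second-order in the interior, first-order in the single voxel layer
touching an electrode), reported in V/cm to sit naturally next to the
400 V/cm IRE threshold, with current density σ|E| in kA/m². Delivered
current is integrated over the line-electrode faces and checked against a
12 A generator compliance; line and neutral currents agree within 0.5% at
the solver tolerance, and the discrete maximum principle holds on every
solve.

Verification is analytic: a parallel-plate slab reproduces E = V/d to
0.1%, and concentric spherical electrodes (a = 2 mm, b = 20 mm at 0.25 mm
spacing) match the 1/r potential within 2% of the applied voltage
everywhere at least one voxel away from the staircased electrode
surfaces — the error is measured relative to the applied voltage because
the local analytic value vanishes at the return electrode.

## The thermal transient

`simulateTransient()` integrates ρc ∂T/∂t = ∇·(k∇T) − ρ_b c_b (u·∇T) + q
with the Joule source q = duty · σ|E|² active only during the burst.
Diffusion is integrated implicitly (backward Euler), which is
unconditionally stable across the large property contrast between
platinum and tissue; advection uses explicit first-order upwinding with a
hard CFL check; an explicit diffusion mode exists and rejects any step
above its stability bound. Defaults are 1 µs steps during the 100 µs
burst and 1 ms during the 0.8 s relaxation (one R-R interval at 75 bpm).
No perfusion sink is applied by default — on a single-burst, sub-second
horizon perfusion is negligible — but a volumetric perfusion rate can be
switched on.

Blood motion is a static analytic laminar profile (`makeFlowField()`):
Poiseuille or plug along the lumen axis for the ostium scenario, a shear
profile rising from the endocardial surface for wall-type scenarios, with
no-slip zeros in blood voxels touching tissue or electrodes. This
replaces a Navier–Stokes solve deliberately: only a static laminar field
enters the physics being exercised, and an externally computed velocity
volume can be substituted.

Probes are conventions, documented rather than inherited: the "tissue
interface" probe tracks the hottest myocardial voxel face-adjacent to an
electrode, the "blood" probe the hottest blood voxel. Printed decay
amplitudes and constants from any particular mesh are not reproducible at
these resolutions and are treated as fit-recovery problems instead (see
below).

Verification: exact equilibrium at zero source; enthalpy gain equal to
the injected Joule energy under adiabatic boundaries (the conservative
finite-volume form makes this exact up to solver tolerance); a 1D
Gaussian excess following the analytic heat kernel within 1% L2; and
flow cooling that is ordered and saturating across the
0 / 0.08 / 0.16 m/s velocity sweep. One caveat worth stating: after a
single 100 µs burst the hottest blood voxel lies in the no-slip layer, so
the *peak* is insensitive to velocity at these resolutions (we assert
non-increase within numerical tolerance); the cooling ordering expresses
itself clearly in the post-burst relaxation, where the marginal benefit
of doubling the velocity visibly shrinks.

## Lesion metrics

* `effectiveFieldRadius()` — the IRE extent. "Radius from the electrode
  surface" is operationalized as the maximum, over super-threshold
  myocardial voxels, of the distance to the nearest electrode-surface
  voxel (a discrete distance transform); the measurement locus is our
  definition. An `inter_electrode` mode measures the mask half-width on
  the mid-plane between the closest line/neutral pair.
* `untreatedGap()` — the longest contiguous sub-threshold myocardial run
  along the inter-electrode axis, sampled at half-voxel steps.
* `alignmentSensitivity()` — the coefficient of variation (sample, n−1
  denominator — the source does not specify) of any scalar lesion metric
  across alignment configurations.
* `fitExponentialDecay()` — nonlinear least squares for
  T(t) = baseline + A·exp(−t/τ) with a log-linear start; constant and
  non-decaying series are rejected rather than fitted.

The 400 V/cm default threshold is exposed for titration studies. The
radius operator is verified against the closed form for an ideal
spherical electrode (E = V·a/r², super-threshold radius √(V·a/E_th))
within one voxel, with a brute-force voxel-scan oracle confirming the
distance computation exactly.

## Volumetrics and statistics

`volumeFractions()` computes the myocardial volume percentage
(Vtot − Vnonmyo)/Vtot × 100 over a labelled specimen (background
excluded), per volume and per slice. Note a sign subtlety: this ratio is
the *myocardial* fraction, while treated/control comparisons are usually
quoted on its complement, the non-myocardial percentage. Both are
returned under unambiguous names; the complement is what
`ablatedFraction()` subtracts (treated minus control, e.g. 20.25% −
9.225% = 11.03% after rounding half away from zero to two decimals —
`round()`'s half-even rule would disagree in the last digit, hence
`roundHalfAway()`).

`extrusionReferenceRatio()` compares the ablated volume against an
individual-specific reference: the loop-catheter footprint π(d/2)²
extruded along the thickest per-slice wall section (maximal inscribed
width, corrected by one voxel for centre-to-centre distances).

Statistical helpers wrap standard machinery: `oneSampleTSummary()` (the
closed form on printed mean/SD/N), `pairedChangeStats()` (paired t by
default, Welch's unpaired variant on request), and `kruskalDunn()`
(tie-corrected Kruskal–Wallis omnibus via `kruskal.test`, Dunn's
rank-based z post hoc written out explicitly with Bonferroni adjustment —
the adjustment family is our choice, as is conservative).

## Synthetic data: what it emulates, what it does not

Generators exist so that every stage has a valid, truth-annotated input:

* `genEcg()` — Gaussian R spikes at a stated rate (default 69 bpm) plus
  noise; optional T-wave bump for gating-failure experiments. It is a
  spike train, not a physiological ECG: no P waves, no baseline wander,
  no morphology variation. Passing gating tests show threshold logic
  works, not that the detector survives clinical artefact.
* `genSegmentation()` — a shell- or slab-shaped myocardial specimen with
  contiguous lesion patches grown by seeded region accretion
  (transmural-scar-like) and salt-scattered native non-myocardium
  (default 9.225%, a typical healthy-control level). Labels only; no MRI
  intensities, no partial-volume effects, no segmentation error — so
  recovery tests measure the estimator, not the imaging chain.
* `genEgmCohort()` — paired electrogram records with configurable
  pre/post means and SDs (defaults follow typical left-atrial effect
  sizes: amplitude 2.20 ± 0.84 → 0.61 ± 0.18 mV, duration 45.29 ± 8.1 →
  58.38 ± 12.61 ms, impedance −31.75 ± 13.92 Ω from a nominal
  110 ± 15 Ω baseline, the baseline being a synthetic convention).
* `genDecaySeries()` — baseline + A·e^(−t/τ)(1 + ε) with defaults
  A = 7.6 °C, τ = 9.22 ms, the tissue-probe scale of a single burst.

All generators are deterministic given a seed.

## Problem sizes, tolerances and limitations

The shipped tests run at desk scale, chosen to finish comfortably on one
CPU: 0.25 mm spacing for analytic solver verification (about 4.4 million
voxels for the concentric-spheres case), 0.5 mm for scenario-level solves
and the thermal velocity sweep (a 60×60×32 atrial-wall grid), 1 mm for
structural checks. Conjugate-gradient tolerances are 1e-8 throughout;
decay-fit recovery is tested over 100 seeded replicates at 1% noise
(median τ error ≤ 2%).

What desk scale cannot do is reproduce mesh-converged field maps from a
finite-element study with sub-voxel electrode detail: printed effective
radii (3 mm / 1.85 mm / 5 mm), decay constants, peak temperatures and
summary-table values depend on exact catheter geometry and meshes we do
not possess. The package therefore treats those as structural targets —
orderings (misaligned septa leave wider untreated gaps), monotonicities
(radius grows with voltage, shrinks with threshold; flow cools), scalings
(q ∝ V²) and report shapes — while the genuinely scale-free quantities
(protocol arithmetic, the volumetric and statistical estimators, analytic
solver limits) are asserted numerically. Fibre-orientation-dependent
thresholds, electroporation pore kinetics, multi-burst cumulative heating
and temperature-dependent tissue properties are out of scope.
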