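---
title: "Simulating the interplay effect in scanned proton therapy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the interplay effect in scanned proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pencil-beam-scanning (PBS) proton therapy delivers dose spot by spot, layer
by layer, over tens of seconds. When the target moves periodically with
breathing, the delivery time structure interferes with the motion: single
fractions develop hot and cold spots inside the clinical target volume
(CTV) even when the time-averaged geometry is perfectly covered. This
*interplay effect* is a major concern for abdominal targets such as
pancreatic tumours, whose dominant inferior–superior (IS) motion reaches
up to ~15 mm with day-to-day variation.

`interplay4d` provides a self-contained simulation laboratory for this
problem: a synthetic abdominal phantom with target and organ-at-risk (OAR)
structures, periodic 20-phase breathing deformation fields, deformation QA,
a simplified analytic PBS dose engine with single-field-uniform-dose (SFUD)
planning and a delivery clock, time-resolved 4D dose accumulation,
stochastic fractionation simulation, dose-volume-histogram (DVH) metrics,
and the weighted-correlation statistics used for cohort-level analysis.

## Coordinate conventions and containers

All volumes live on one shared regular grid with axis order (LR, AP, IS),
millimetre world coordinates at voxel centres, and positive directions
toward patient-left, anterior, and superior. Images and dose grids are
`voxel_grid` objects; deformation vector fields (DVFs) are
`deformation_field` objects holding a 3-vector per voxel.

DVFs use pull-back semantics: the field of breathing phase `j` maps
reference (end-exhalation, EEX) positions to sampling positions, so the
phase image is `CT_j(x) = CT_EEX(x + u_j(x))`. Phase 0 is EEX and carries
an exactly zero field. Trilinear interpolation is used for images and dose,
nearest-neighbour for binary masks (ties at 0.5 resolve toward inclusion),
and out-of-grid samples take the air value (−1000 HU).

## The synthetic patient

`build_phantom()` voxelizes geometric primitives into an HU volume and a
structure set: a soft-tissue body, a vertebral body with the spinal cord
posterior to the target, kidneys lateral-posterior, liver right-superior,
bowel anterior, and an ellipsoidal CTV (pancreas) anterior to the vertebra.
The CTV semi-axes are solved from the requested volume (default 51.9 cc) at
a fixed aspect ratio; the voxelized volume must land within 5% of the
request or the configuration is rejected. The default grid is 96³ voxels at
2.5 mm; all organ positions scale with the field of view so the same
anatomy runs at reduced sizes (the tests use 40–64 voxels per axis).

`generate_motion_input()` builds one breathing "measurement": separable
fields `u_j(x) = s_j · U(x)` with

* a spatial envelope `U` that is ~1 near the CTV, falls smoothly to zero at
  the posterior spine region and at every grid face (so boundary voxels
  never move), scaled per axis to the requested amplitudes — defaults
  follow the patient-like regime of dominant IS motion (≤ 15 mm) with
  AP/LR amplitudes around a third of IS;
* a temporal factor `s_j = sin²(π j / 20)` sampled at 20 uniform time
  points of one cycle — EEX at phase 0, end-inhalation (EIN) at phase 10;
  regular breathing only.

The generator verifies the requested amplitude is reproduced at the CTV
centroid within 5% and that every phase field is fold-free (Jacobian
determinant > 0 everywhere), refusing amplitudes that would fold the
envelope. Breathing periods are restricted to [2.8, 10] s. Day-to-day
variation is emulated two ways, mirroring how repeated measurements differ:
independently generated patterns with different amplitudes, and
`rescale_period()` copies that change *only* the breathing period, leaving
amplitudes untouched — the intra-patient amplitude-period relation is
deliberately not modelled.

Twenty phases uniform in time are an assumption (time-binning versus
amplitude-binning of a 4D acquisition is not standardized); amplitude
binning would mildly reweight mid-cycle geometries but not change the
mechanism under study.

The ITV is the union of the CTV warped to all phases of the scenario's
*first* motion input (the "planning" acquisition — later repeated
measurements do not reshape target volumes, as in clinical practice), and
the PTV adds a 5 mm isotropic margin as a Euclidean ball in mm.

## Deformation QA

`jacobian_determinant_map()` evaluates det(I + ∇u) per voxel with central
differences in physical mm (one-sided at boundaries). The
mass-conservation check multiplies organ volumes by densities from a
piecewise-linear HU-to-density table with nodes (−1000, 0.001),
(−100, 0.93), (0, 1.0), (100, 1.09), (1000, 1.6): `m_EEX` integrates
density over the organ mask, `m_EIN` over the mask warped EEX→EIN with the
warped HU. Pure intensity warping does not conserve mass — with the
pull-back convention a linear field of Jacobian determinant J shrinks the
warped delineation by J at unchanged density, so the ratio `m_EEX/m_EIN`
equals J. The density of the warped phase is sampled from the warped CT
(the only CT that exists in a synthetic setting).

## The dose engine

The engine is a deliberately simplified, fully parameterized stand-in for a
clinical analytic PBS engine; the study's claims concern interplay
*statistics*, not absolute dosimetry.

* **Range–energy**: `R[cm] = 0.0022 · E^1.77` (water, E in MeV).
* **Depth dose**: an analytic Bragg shape — flat entrance plateau (32% of
  peak) plus a Gaussian-capped peak at `R(E)` whose width is 2.5% of the
  range (an effective peak width, standing in for straggling plus the
  energy spread/ridge-filter broadening of delivered beams), a steeper
  Gaussian distal falloff, exactly zero beyond the distal tail, normalized
  to 1 at the peak.
* **Lateral model**: a single 2D Gaussian with `σ(wepl) = 3 mm +
  0.025·wepl`.
* **WEPL**: radiological depth is traced by resampling density (the
  HU-density table doubles as relative stopping power) onto a beam-aligned
  (BEV) grid and integrating along the beam axis with midpoint cumulative
  sums. The gantry rotates in the axial plane; BEV axes are right-handed
  (lateral-in-plane, IS, beam direction).
* **Delivery dynamics**: spot dwell = weight / dose rate, with the dose
  rate calibrated so the mean dwell is 5 ms; 3 ms lateral moves; 1 s energy
  layer switches; layers delivered in descending energy with serpentine
  scanning. Typical two-field plans take ~15–20 s per field, the right
  order for interference with 2.8–10 s breathing cycles.

`plan_sfud()` places spots on a 5 mm lateral grid and 5 mm WEPL-spaced
energy layers covering the PTV expanded by an 8 mm optimization margin, and
optimizes non-negative spot weights per field (each field alone delivers a
uniform half-prescription) by accelerated projected gradient (FISTA) — a
non-negative least-squares solve capped at 1000 iterations with a 1e-4
relative-residual stop. Optimization points in the shell outside the PTV
get a 3% boosted target (edge enhancement): a plain least-squares fit lets
the field edge sag by a few percent, which would erode the accumulated
coverage of CTV voxels that spend part of the cycle near the ITV boundary.
Plans are calibrated so the static CTV median dose is 100% of prescription;
on the default phantom the static plan reaches v95 = 100%, v107 = 0%, and
d5/d95 ≈ 1.03, matching the intended static-plan regime. Prescriptions
default to 1.8 Gy(RBE) × 28 fractions at a constant RBE of 1.1; doses are
reported in % of prescription throughout.

## 4D dose accumulation

`assign_spots_to_phases()` maps each spot timestamp to a breathing phase:
`phase(t) = (start + ⌊20 t / T⌋) mod 20`, i.e. phase bins uniform in time.
`compute_4d_dose()` then deposits each phase's spot subset on that phase's
geometry — the reference CT warped by the phase field, with WEPL re-traced
on the warped CT (density change along the beam path is the physical
mechanism) — and pulls the phase dose back to the reference frame by
sampling at `x + u_j(x)`. Fraction dose is the sum over phases and fields.
No intra-spot motion: a spot's dwell (ms) is far below a phase bin width
(140–500 ms). Dose pull-back is plain trilinear sampling without mass
reweighting; the QA module quantifies the induced mass error instead.

For ensembles, `interplay_table()` evaluates the same per-point formula
directly at the structure voxel positions (an exact restriction of the full
computation, skipping the intermediate BEV dose grid that the full path
must resample), precomputing per field, motion input and starting phase the
dose at every tracked point. Every fraction dose is then a sum of two
vectors, so 20×20 starting-phase ensembles, 28-fraction treatments and
30-treatment experiments cost vector arithmetic. The analytic static dose
at the same points is stored as the consistent static reference: the
full-grid path smooths steep gradients through the BEV grid resampling, so
mixing the two conventions would bias static-versus-4D comparisons by a few
percent at dose edges. Phases that share a temporal factor (the sin²
waveform pairs j with 20−j) share warped geometry via caching.

Starting phases `(i, k)` of the two fields are independently uniform per
fraction — the second field does not continue the breathing clock of the
first, since repositioning gaps between fields are long and variable
relative to a breathing cycle. The single-fraction ensemble enumerates the
full 20×20 grid of pairs by default (`combination = "diagonal"` gives the
20 synchronous pairs).

`simulate_treatment()` draws, independently per fraction, a motion input
(uniform over the available measurements) and a starting-phase pair, and
accumulates; cumulative dose after n fractions is reported in % of the
prescription delivered so far (the mean of the first n fraction doses), so
metrics are comparable across n. Realizations are deterministic given a
single integer seed. OAR metrics are computed per realization at
(subsampled) OAR points when requested; the CTV is never subsampled.

## Metrics and statistics

`dose_percentile()` (dN) uses the descending-sorted voxel list with linear
interpolation between adjacent voxels — the convention is documented
because d5/d95 must be bit-reproducible from a dose vector. vL is the
percentage of voxels at or above the level. DVH exports use 0.1%-wide bins;
queries never touch the binning. Scenario comparisons (3DDC vs 4Dx1 vs
4Dx28) use one-sided Wilcoxon rank-sum tests at α = 0.05 — exact null for
combined samples of at most 20 without ties, normal approximation with tie
correction otherwise; fully tied samples return the p = 0.5 convention,
flagged.

`weighted_pearson()` uses frequency-weight semantics (weights as
replication counts — the number of repeated motion measurements per
patient), verified against an explicit replication oracle. Significance
uses `t = ρ√((N−2)/(1−ρ²))` against the one-sided 95% Student-t quantile.
The printed critical value 1.833 corresponds to df = 9 while the statistic
uses N − 2 = 7 degrees of freedom (quantile 1.895); both are exposed, and
df = 9 is the default so the tabulated value is reproduced — the
discrepancy is inherited from the source convention, not resolved by
guessing. The CTV-volume correlation is unweighted: volumes are constant
across measurements, so replication counts carry no information for it.
Intra-patient dependencies are reported descriptively only; no coefficients
are fitted to samples of 2–6 points.

## What the synthetic study does and does not show

The generator emulates: patient-like amplitude ranges and periods,
day-to-day motion variation, 20-phase periodic sampling, HU heterogeneity
along the beam path (soft tissue, bone, air outside the body). It does not
emulate: irregular or drifting breathing, baseline shifts, amplitude-period
coupling, inter-fraction anatomy changes (same phantom every day),
registration error (fields are known analytically, so QA passes by
construction rather than measuring a registration), or realistic nuclear
halo/heterogeneity scattering physics. Passing tests therefore demonstrate
the *mechanism and statistics* of interplay and its fractionation
mitigation under controlled conditions, not clinical dosimetric accuracy
for any patient.

## Numerical choices

* Trilinear/nearest interpolation as above; warped-mask volumes are
  cross-checked against analytic expectations in the tests.
* Finite differences in mm; one-sided at boundaries.
* FISTA step size from 25 power iterations; weights start at zero;
  spots below 1e-6 of the maximum weight are pruned.
* Lateral Gaussians truncated at 3.5σ in deposition and influence matrices.
* The folding check evaluates det(I + s·∇U) at the worst-case |s|.
* Problem sizes: unit tests run 40³ phantoms (6 mm); the acceptance-style
  checks use 96³ × 2.5 mm for the static-limit identity, 64³ × 3.75 mm for
  the fractionation experiment (24 simulated 28-fraction treatments), and
  48³ × 5 mm for the amplitude sweep and the longitudinal comparison (30
  treatments per arm) — chosen as the smallest grids that leave the
  studied effects comfortably above discretization noise.

## Known limitations

* Density is used as relative stopping power; no nuclear buildup, halo, or
  aperture modelling — absolute OAR doses are indicative only.
* The delivery model serializes spots with fixed move and switch times; no
  spill structure or beam-current variation.
* Mask warping is nearest-neighbour; sub-voxel target edges are quantized
  at coarse grids.
* The longitudinal experiment shares one phantom across "days"; it isolates
  motion-pattern variation from anatomic variation by design.
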