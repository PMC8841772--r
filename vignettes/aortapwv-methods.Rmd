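---
title: "Measuring local aortic pulse wave velocity from ultrafast curved-array ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring local aortic pulse wave velocity from ultrafast curved-array ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortapwv)
```

## The measurement problem

Aortic pulse wave velocity (PWV) — the speed at which the systolic pressure
pulse travels along the arterial wall — is a primary mechanical surrogate of
arterial stiffness. Measuring it *locally* in the abdominal aorta requires
imaging a deep, wide field of view at kilohertz frame rates, because the
pulse crosses a 60 mm segment in 5–20 ms. `aortapwv` implements the full
measurement chain on top of a synthetic-phantom generator, so every stage is
testable against known ground truth without any external data:

1. **Acquisition model** — tilted diverging waves (virtual point sources on
   the probe's curvature circle, default steering angles −12°, 0°, +12°)
   received by a convex array, delay-and-sum beamformed on a polar grid and
   coherently compounded.
2. **Wall motion tracking** — 1-D normalized cross-correlation (NCC) of RF
   speckle along each scanline with an adaptive reference frame: when the
   running correlation drops below a threshold (default 0.9) the reference
   is replaced by the current frame and inherits the accumulated
   displacement, limiting drift from progressive decorrelation
   (out-of-plane motion).
3. **PWV imaging** — the tracked displacement is differentiated in time with
   a 9-point Savitzky–Golay filter, producing a 2-D (position × time)
   wall-velocity map; the 50%-upstroke crossing of each systolic wave is the
   arrival marker; ordinary least squares of arrival time on distance gives
   PWV = 1/slope, gated by r² ≥ 0.5; cycles are averaged.
4. **Theoretical reference** — the Bramwell–Hill relation
   `PWV = sqrt(A_d · PP / (ρ · ΔA))` from diastolic area, systolic–diastolic
   area difference and local pulse pressure (ρ = 1060 kg/m³), plus the
   cohort statistics used to relate PWV to cardiovascular risk strata
   (Kruskal–Wallis with Dunn–Bonferroni post hoc, Welch's t, Pearson r,
   Bland–Altman agreement).

## The phantom: what it emulates and what it does not

`generate_wall_displacement_field()` prescribes the kinematic ground truth:
a straight horizontal vessel whose walls distend under a pulse travelling at
`pwv_true`. The single-cycle wall-velocity pulse is a raised-cosine upstroke
(duration `rise_time`, default 60 ms) followed by an exponential decay
(`decay_time`, 150 ms); its 50% upstroke crossing is analytically
`foot + rise_time/2`, which is what makes the systolic-foot detector
testable to sub-frame accuracy. When the cardiac period is finite, each
systolic lobe is followed by a shallow raised-cosine diastolic recoil sized
so the cycle's displacement integral closes exactly to zero — the wall
returns to its diastolic position every cycle, as an elastic vessel must
(without it, displacement ratchets by ~0.45 mm per cycle, walks the
scatterers out of the recorded time window and makes the three cycles
progressively noisier). Displacement is the exact closed-form time
integral, so the pure-delay property `d(x, t) = d(0, t − x/pwv)` holds
analytically, not only on the sample grid. Defaults follow the acquisition
protocol the method targets: 1 kHz frame rate, 3 cardiac cycles in a 3.0 s
recording (heart rate 60 min⁻¹), a 60 mm segment, peak lumen-distension
velocity 5 mm/s (≈0.9 mm diameter change on an 18 mm aorta — a moderately
stiff adult vessel), walls at 55 and 75 mm depth.

RF rendering (`render_rf_sequence()`) is far-field point-scatterer
superposition: every scatterer contributes one Gaussian-enveloped carrier
pulse per transmit/element at its round-trip delay, with a soft-baffled
piston receive directivity (`sinc(w·sinφ/λ)·cosφ`, element width 0.9 ×
pitch). Out-of-plane motion is modelled as amplitude-preserving random
replacement of a fraction of scatterers per frame — it produces the
controlled, monotone correlation decay the adaptive tracker must survive,
without modelling elevational beam physics. There is no attenuation, no
phase aberration, no reverberation and no electronic-noise model unless
`noise_sd` is set; passing the recovery tests therefore demonstrates the
correctness of the measurement chain, not robustness to everything clinical
imaging can produce.

`render_speckle_lines()` is a documented fast path that synthesizes
per-scanline speckle directly on the beamformed grid (Gaussian envelope,
two-way carrier), bypassing diffraction. It exercises the tracker at scales
where full rendering is unnecessary (e.g. hundreds of seeded decorrelation
phantoms).

## Numerical choices that matter

**Sub-sample interpolation and the running correlation.** The beamformed RF
is sampled at λ/8 along the scanline, so the two-way carrier spans four
samples. Two consequences are handled explicitly. First, the NCC of
broadband RF evaluated on the integer lag lattice *undershoots* the true
correlation peak by up to ≈cos(π/4) ≈ 0.71 whenever the true shift sits
near a half-sample — purely a sampling artifact. The adaptive-update
decision therefore gates on the sub-sample-refined peak magnitude (a
three-point cosine-envelope fit), while `correlate_window()` still reports
the raw integer-peak coefficient. Gating on the raw lattice value fires
thousands of spurious reference updates during every systolic excursion,
and each update freezes one frame of motion into the inherited offset —
the accumulated drift destroys the arrival-time map. Second, the peak
*location* is refined by a three-point fit: `correlate_window()` defaults
to the textbook parabola, but the tracker's default is the cosine model,
which is markedly less biased on carrier-dominated correlation functions
(≈0.25 µm vs ≈1 µm RMS on rendered phantoms). A carrier-phase refinement
(`"phase"`) is also available; it is the lowest-bias option when the
beamformed carrier matches the nominal `4π·dz/λ` exactly (true for the
directly synthesized speckle lines) but tilted-transmit compounding
detunes the carrier enough that the self-calibrating cosine fit wins on
beamformed data.

**Displacement chaining across reference updates.** A new reference
inherits the last accepted absolute displacement; the triggering frame's
displacement equals that offset (it correlates with itself at lag zero).
This is the only choice that keeps displacement continuous, at the cost of
freezing one frame of motion per update — the reason spurious updates must
be rare.

**Regression distance.** Scanlines are placed so that their intersections
with the straight vessel reproduce the phantom's lateral positions, and
that exact abscissa is the regression distance. (Arc length at the wall
depth differs from it by up to ~1.5% at the sector edges; using the true
intersection abscissa removes that known geometric bias.)

**Regression direction.** Arrival time is regressed on distance and
PWV = 1/slope (the alternative direction is available via
`fit_pwv(..., direction = "distance_on_time")`). For clean data the two
agree; under arrival-time noise the default direction is the one whose
*slope* noise is attenuated, and its residual convexity bias
(E[1/ŝ] > 1/E[ŝ]) is below 1% at the r² values the gate accepts.

**Cycle windows and the 50% level.** Cycle windows come from
prominence-based peaks of the spatially averaged velocity; the 50% level is
measured from the pre-upstroke local minimum within the window (robust to
the previous cycle's decay tail, which is itself shift-invariant across
positions). Multiple crossings: the first wins — the systolic foot is the
earliest feature. Positions with peak velocity below 10% of the map's
global peak are flagged invalid; the threshold is a package choice, not a
protocol value.

**Boundary handling.** The Savitzky–Golay differentiator uses the filter
matrix's polynomial boundary fits for edge frames. The tracker shrinks the
search range near the ends of the beamformed depth band rather than
zero-padding, so lags stay alignment-exact.

## Reduced-scale study conditions

The end-to-end recovery experiments run the full chain — render, beamform,
track, estimate — at a deliberately reduced acquisition scale chosen once:
64 elements at 0.75 mm pitch (47 mm aperture), 64 scanlines over the 60 mm
segment, posterior wall only, ~1000 scatterers in a 1.5 mm wall band, RF at
20 MHz for a 5 MHz carrier, beamformed over a 5 mm band around the wall.
The element count is the one reduced-scale parameter that cannot be pushed
further without changing the physics: a sparse receive aperture raises the
incoherent side-lobe pedestal, so each tracking window admits clutter from
wall speckle many millimetres away laterally. Measured on the phantom, the
clutter-to-signal energy ratio in an 8λ window is ≈48% for 32 elements at
1.5 mm pitch, ≈14% for 48, ≈2% for 64 at 0.75 mm and ≈0.7% for the full
128-element array. Because that clutter carries the wall waveform of
*other* lateral positions, it pulls every line's measured arrival time
toward the regional mean — compressing the time–distance slope and biasing
PWV high by ~8% (and up to 20% on unlucky speckle realizations) at 32
elements, independent of the tracker. 64 elements is the smallest aperture
whose clutter floor no longer dominates the arrival-time budget. Aperture
obliquity matters too: a 32-element aperture at the native 0.6 mm pitch
spans only 19 mm and views the sector edges so obliquely that vertical wall
motion under-reads by ~5% at the segment ends. The full-array default
(`make_geometry()`) remains 128 elements at 0.6 mm pitch; these are generic
convex-array values, not a specific clinical probe's geometry.

Even at 64 elements a residual overestimation of roughly +4–8% remains on
the full RF path (the displacement-field path and per-scanline speckle
path are unbiased, so it originates in the beamformed image formation).
It is speckle-realization-dependent but reproduces with the same scatterer
seed across different array geometries, flips sign with the wave's travel
direction, and is insensitive to grating-lobe suppression, aperture width
and the sub-sample interpolator — consistent with a weak pull of each
scanline's arrival time toward its PSF-correlated neighbourhood. The
recovery tests therefore check the full RF path against a 10% band and the
idealized displacement path against 3%; both bounds hold with margin at
the stated scale.

## The risk-stratified cohort generator

`generate_cohort()` draws three risk strata (10-year risk score < 10%,
10–20%, > 20%; boundary values belong to the middle band) with sizes
31/22/16 and per-group PWV means/SDs at the method's reference operating
point (imaging PWV 5.3 ± 1.1, 8.3 ± 3.1, 10.8 ± 2.5 m/s; theoretical PWV
5.1 ± 0.9, 7.7 ± 2.0, 9.8 ± 2.5 m/s). Within a group the two measures are a
bivariate normal with correlation 0.85, and each subject's diameters are
derived from their theoretical PWV and pulse pressure through the
Bramwell–Hill relation, so the tabulated diameters, pressures and PWVs are
mutually consistent by construction. The statistical battery's power
properties on this generator (group separations detected, correlation
recovered) say nothing about any clinical population — they verify the
implementation at its stated operating point.

## Known limitations

- The acquisition model omits attenuation, aberration and elevational
  physics; decorrelation is a statistical surrogate for out-of-plane
  motion.
- The three tilted transmits of a compounded frame observe the same wall
  state; intra-triplet pulse-repetition timing is not modelled.
- Tracking is axial-only (along the scanline); lateral motion appears only
  as decorrelation, which is the mechanism the adaptive reference is
  designed to absorb, not correct.
- The straight-vessel distance coordinate ignores vessel curvature; the
  segmentation is a two-peak envelope heuristic, adequate for the phantom's
  well-separated walls, not for pathology.

## Reproducing the numbers

`scripts/acceptance.R` re-runs the whole chain from scratch — phantom
recovery at 3/5/8/12 m/s through both the displacement-field and the full
RF path, the adaptive-vs-fixed reference comparison across seeded
decorrelation phantoms, the sub-sample tracker oracle, the differentiator
and Bramwell–Hill checks, the r²-gate rejection rate and the cohort
statistics — and writes one JSON object of measured quantities. Problem
sizes are the reduced-scale conditions above; a run takes a few minutes on
one CPU.
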