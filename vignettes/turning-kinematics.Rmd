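---
title: "Methods: segmenting and quantifying 360-degree turning from four IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and quantifying 360-degree turning from four IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnkin)
```

## The measurement model

A turning trial is recorded by four inertial measurement units — sternum,
sacrum, left shank, right shank — each reporting 3-axis angular velocity
(°/s) and orientation angles (°) at 60 Hz. All channels are stored with
anatomical semantics (flexion–extension, lateral bending, axial rotation);
the mapping from device axes is applied once at ingest (`axis_map()`), so no
downstream code depends on sensor mounting. Linear acceleration is out of
scope: an on-spot turn involves little translation, so only angular
parameters are analyzed.

Two assumptions drive the segmentation design:

1. **The leading shank swings in a recognizable pattern.** During a turn the
   leg that initiates it (the unaffected side in stroke survivors) steps
   repeatedly; each swing produces a bell-shaped pulse in the
   flexion–extension angular velocity, separated by stance intervals near
   zero. Gait events are therefore recoverable from this one channel.
2. **The trailing shank rotates monotonically through ~360°.** Its
   flexion–extension pattern is unreliable on the affected side, but its
   axial-rotation angle accumulates the full turn, so the turn can be divided
   *spatially* into equal angular partitions regardless of stepping pattern.

## Temporal segmentation

The leading-shank flexion–extension angular velocity is low-pass filtered
(4th-order Butterworth, 5 Hz cut-off) and sign-normalized so swing peaks are
positive. Mid-swing events are local maxima with topographic prominence of at
least `prominence_frac` (default 0.3) of the global maximum, separated by at
least `min_separation_s` (default 0.3 s, below any plausible turning cadence;
the taller peak wins a conflict). For each peak, the swing onset and offset
are first located where the signal falls below `onset_frac` (default 0.1) of
that peak's height.

A raw threshold crossing is biased inward: for a raised-cosine pulse of width
$w$, the crossings at height fraction $q$ sit $u(q) = \arccos(1-2q)/(2\pi)$
of the width inside each edge ($u(0.1) \approx 0.102$), which would inflate
the stance estimate by ~10 percentage points at typical swing widths. Since
the detector's model is precisely a bell-shaped pulse, the default
(`extrapolate_base = TRUE`) widens the crossing interval by $u/(1-2u)$ on
each side, placing toe-off and heel-strike at the estimated pulse base. The
residual bias that remains comes from the 5 Hz filter widening short pulses;
on 100-trial synthetic cohorts per group at default noise the mean absolute
stance error is under 3 percentage points (the acceptance suite recomputes
this). Walking outward to the nearest local minimum instead was rejected: it
chases the filter's decay tail into the noise floor and biases stance the
other way by a comparable amount.

Derived parameters: the **cycle count** is the number of mid-swing events;
the **turn duration** runs from the first toe-off to the last heel-strike
(the turn boundaries are otherwise undefined by the task); a **cycle** is
defined toe-off → toe-off so that its stance phase, heel-strike to the next
toe-off, lies wholly inside it. With $n$ swings this yields $n-1$ stance
values,

$$\mathrm{stance}_i = \frac{\mathrm{TO}_{i+1} - \mathrm{HS}_i}
                           {\mathrm{TO}_{i+1} - \mathrm{TO}_i} \times 100\,\%;$$

a heel-strike at or after the next toe-off flags that cycle invalid (it is
excluded and logged). With fewer than two swings the stance fraction is
undefined and a warning is raised. The stance percentage is the leading-leg
swing complement — foot-contact sensing is absent in this configuration, so
bilateral double-support cannot be measured; this is a documented convention,
not an approximation of it.

## Spatial segmentation

The trailing shank's axial-rotation angle is unwrapped (jumps > 180° between
samples), zero-based, and sign-flipped so the turn is positive for either
turning direction. The per-trial total rotation is *measured* (participants
cover approximately, not exactly, 360°). Small noise dips are removed with a
running maximum before crossing detection; a dip larger than `backtrack_tol`
(10°) rejects the series as non-monotone, and a total below 90° raises a
"no turn detected" error.

Partition $j$ of $k$ ends where the rotation first reaches $j \cdot
\theta_{\mathrm{total}}/k$. Crossings are located with sub-sample linear
interpolation and then snapped to the nearest sample: at 60 Hz a brisk ~4 s
turn sweeps several degrees per sample, so "first sample at or above the
target" alone would quantize boundary angles by more than the 2° accuracy the
package aims for. The turn interval itself runs from the first sample above
`angle_eps` (2°) to the first sample within `angle_eps` of the total.
Partitions tile the turn exactly — partition $j$ covers samples
$[b_j, b_{j+1})$, the last closes the interval — so duration-weighted
per-partition means reconstruct whole-turn means identically. All
$k \in \{2,\dots,7\}$ are supported; tables are emitted for the configured
set (default $k = 2$ and $k = 4$, the 180° and 90° divisions).

## Kinematic parameters

For every interval (whole turn or partition), per segment and direction:

- **Mean absolute angular velocity**, $\overline{|\omega|}$. The mean of the
  *absolute* signal is used because an oscillating segment's signed mean
  cancels toward zero while the published group values are all positive.
- **Range of motion**, $\max(\theta) - \min(\theta)$ of the orientation
  angle (the field's convention; no detrending).
- **Relative sternum−sacrum measures**: the per-sample difference signal is
  formed first and then summarized. Summaries of differences are not
  differences of summaries; the per-sample form is what captures
  inter-segment (a)synchrony.
- **Leading/trailing ratios** of the shank summaries; a near-zero
  denominator flags the record undefined (excluded and logged) rather than
  producing an unbounded value.

All channels used for feature extraction are filtered with the same 5 Hz
zero-phase low-pass for consistency; trunk parameters in the temporal scheme
are computed over the full turn rather than per gait cycle (the trunk's
oscillation need not be phase-locked to the leading leg).

## Group comparison

Each parameter is compared between groups with an unpaired two-tailed
t-test; pooled-variance Student's t is the default with Welch's correction
selectable. If both groups are constant, p is 1 when the means agree and 0
otherwise, by convention. No multiple-testing correction is applied (α =
0.05 per test), matching standard practice for this table family; readers
should treat borderline p-values accordingly — a documented limitation.

Two percent-difference conventions appear in this literature and both are
exposed:

- `pct_diff_reference(a, ref)` $= (a - \mathrm{ref})/\mathrm{ref} \times
  100$, for statements like "67% more cycles";
- `pct_change_symmetric(x1, x2)` $= (x_2 - x_1)/\tfrac{x_1 + x_2}{2} \times
  100$, the midpoint-referenced change used between consecutive partitions.
  It is antisymmetric and bounded by ±200 for same-sign inputs. This
  convention was identified by recomputing every printed partition-comparison
  cell of the reference study's spatial tables from their printed means: all
  200 cells reproduce within ±1 (the transcribed tables ship in
  `inst/extdata/` and the check runs in the test suite).

## The synthetic-trial generator

Real recordings from the motivating study are available only on request, so
validation rests on synthetic trials with exact ground truth
(`generate_trial()`, `generate_cohort()`). Construction:

- **Leading shank flexion–extension**: a train of `n_cycles` raised-cosine
  pulses. The raised cosine is the package's concrete choice of "bell
  shape": smooth, compactly supported, with analytic boundaries and
  integrals. Cycle period, pulse width, and peak are set by the drawn
  duration, stance fraction, and swing peak; the angle channel is the exact
  pulse integral, so gyro and angle are mutually consistent.
- **Trailing shank rotation**: a monotone S-curve ramp
  $\theta(\tau) = \theta_{\mathrm{total}}(\tau - \sin(2\pi\tau)/2\pi)$ with
  zero end slopes, covering a total drawn uniformly in [340°, 380°] (signed
  by turn direction) and stored wrapped to ±180° as an orientation sensor
  reports yaw. Its analytic inverse provides the oracle for partition
  boundary times.
- **All other channels**: cosine oscillations whose frequency is snapped so
  an integer number of half-periods spans the turn; the realized range of
  motion then equals the drawn ROM exactly and the mean absolute angular
  velocity equals $2 \cdot \mathrm{ROM} \cdot f$ analytically. Outside the
  turn all channels hold their endpoint values (quiet standing, ≥ 1 s
  padding on each side).
- Zero-mean Gaussian noise (default SD 0.1 °/s and 0.1°) is added per
  channel — small relative to the ~7 °/s swing pulses but visible at the
  trunk-velocity scale.

Group profiles are truncated normals. Cycle count, duration, and stance
fraction use the reference study's printed group means and SDs (SS:
5.86 (1.56) cycles, 7.67 (3.17) s, 53.28 (13.59)%; HI: 3.5 (0.94),
3.72 (1.74) s, 38.96 (12.57)%); trunk ROM/velocity scales use the printed
per-segment values where available. Truncation bounds are implementation
choices that keep draws physical (≥ 2 cycles — a turn needs multiple steps;
duration well above zero; stance within (0.05, 0.95)); the cycle count is
drawn continuously and rounded. Swing-peak defaults (≈ 7 °/s) were chosen
once so the implied whole-turn mean |ω| of the leading shank,
$\approx A(1-s)/2$, lands at the printed 1.7–2.2 °/s scale. A profile whose
bounds exclude essentially all mass errors out after 1000 rejected draws
rather than looping.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: multi-body biomechanical consistency between segments
(channels are independent given the drawn parameters, and only the trailing
shank carries the full rotation ramp), pulse-to-pulse variability within a
trial (one swing amplitude and stance fraction per trial), asymmetric or
pathological waveform shapes beyond group-level parameter shifts, sensor
drift, and soft-tissue artifact. Note also that the printed angular-velocity
magnitudes in the reference tables (≈ 0.1–2 °/s) are small for a turning
task relative to the printed ROMs and durations; the generator adopts them
as configurable scales for worked-example arithmetic without asserting
physical plausibility, which is why a drawn (ROM, velocity) pair whose
implied oscillation would not fit a single half-period in the turn is
realized at the nearest feasible frequency, with the realized values — not
the drawn ones — recorded as ground truth.

## Numerical choices

- **Zero-phase filtering** is the default so event times carry no group
  delay; forward–backward application squares the magnitude response
  (documented; the single-pass response is available with
  `zero_phase = FALSE`). The implementation pads with odd reflection sized
  from the slowest filter pole (transient decay < 1e-12) and subtracts the
  first sample before filtering so the zero initial condition is exact at DC;
  off-the-shelf forward–backward filtering with zero initial conditions bends
  signals with large offsets or net drift (such as a 360° rotation ramp) by
  tens of degrees at the edges.
- **Analytic filter reference**: checks compare measured sine attenuation
  against the designed digital filter's transfer function evaluated on the
  unit circle (`lowpass_gain()`). At 20 Hz with a 5 Hz cut-off at 60 Hz
  sampling, the bilinear transform's frequency warping makes the digital
  response several times smaller than the continuous-time Butterworth
  magnitude formula; the digital transfer function is the correct oracle
  for the implemented filter, and the continuous formula is used only in the
  passband where the two agree.
- **Unwrapping** uses a 180° jump threshold; at 60 Hz even the fastest
  observed turns move ~6°/sample, far below it.
- **Determinism**: every generator call takes an explicit seed; cohort
  members get seeds derived from the master seed; the pipeline manifest
  records the seed and a configuration hash, and reruns are byte-identical.
  Generators restore the caller's RNG state.

## Problem sizes used in validation

The test and acceptance suites validate recovery on 100 synthetic trials per
group (cycle-count accuracy, stance MAE, duration error, partition-boundary
angle error against the ramp's analytic inverse), calibrate the type-I error
of the group comparison on 500 replicate null cohorts of 14 + 14 trials
drawn from a single profile, and check the t-test against a closed-form
pooled oracle on 1000 random small samples. These sizes give Monte-Carlo
standard errors comfortably below the acceptance margins (e.g. ±2 SE ≈ ±0.02
around α = 0.05 for 500 replicates) while keeping the default suite fast.

## Known limitations

- Stance is the leading-leg swing complement, not bilateral double support.
- The anatomical relabeling at ingest is a convention; the vendor's Euler
  sequence and sensor-to-segment alignment are not reconstructed.
- The printed p-values in the reference temporal table are not exactly
  reproducible from the printed means and SDs at n = 14 per group under
  either pooled or Welch assumptions; they are shipped as transcribed but
  are not used as validation targets.
- Comparison tables are emitted tidy (long format) rather than in the
  publication's wide layout; the column semantics are preserved and the
  partition-comparison columns are recomputable from the stored means.
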