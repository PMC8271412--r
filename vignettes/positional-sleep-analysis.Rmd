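---
title: "Angle-resolved sleep position and positional desaturation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-resolved sleep position and positional desaturation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnpose)
```

This vignette documents the methods behind `somnpose`: the orientation
model and its assumptions, the tunable constants and why they take the
values they do, what the synthetic-night generator does and does not
emulate, the numerical choices made where the underlying procedure was
ambiguous, and the package's known limitations.

## Orientation model

A device worn flat over the sternum measures the gravity vector in the
body frame: X right→left, Y toe→head, Z front→back. The in-plane
orientation angle is

$$\mathrm{angle} = \frac{180}{\pi}\,
  \arccos\!\left(\frac{x}{\sqrt{x^2+z^2}}\right)\,
  \mathrm{sign}(c) + \theta_\mathrm{initial},$$

evaluated on (X, Z) with $c = Z$ for the *sleep angle* (0° left, 90°
supine, ±180° right, −90° prone) and on (Y, Z) with $c = Z$ for the
*stand angle* (±90° laying, ±180° standing, 0° headstand). The formula is
scale invariant, so g and m/s² inputs give identical angles;
`read_accel(units = "ms2")` merely normalises stored values.

Assumptions worth stating explicitly:

- **Gravity dominance.** The accelerometer signal is treated as gravity
  plus noise; the 60-s median filter removes respiration, cardiac motion
  and brief repositioning transients. Sustained non-gravitational
  acceleration (a car, a boat) would corrupt the angles.
- **Supine start.** $\theta_\mathrm{initial}$ is estimated per recording
  as the offset mapping the circular mean of the first 600 s to 90°,
  separately for sleep and stand angles. This presumes the wearer settles
  supine for the first 10 minutes. Recordings that violate it should use
  `auto_calibrate = FALSE` with explicit `--theta-sleep` / `--theta-stand`
  overrides (exposed both in `compute_angles()` and the CLI).
- **Degenerate vectors.** A zero in-plane vector has no orientation; such
  samples yield `NA` and are flagged `valid = FALSE` rather than raising
  (the vectorised translation of a per-sample error), and are excluded
  from every downstream statistic.

Numerical conventions: angles live on the half-open interval (−180, 180]
with −180 mapped to +180, so the pure-right position has one
representation; $\mathrm{sign}(0)$ is defined as +1, placing $Z = 0$
boundary cases on the positive side. Interpolation onto the uniform 10 Hz
grid is linear per axis — at 10 Hz with a subsequent 60-s median filter,
anything fancier is indistinguishable. The median filter truncates
(shrinks) its window at the series edges instead of padding; interior
points are computed by `stats::runmed` and the two edge regions are
recomputed explicitly so the whole series matches the truncated
definition exactly. Whether filtering should precede or follow
interpolation is ambiguous in principle; the package interpolates first,
matching the order in which a streaming implementation would operate.

## Discrete positions and summaries

The discrete boundaries are quadrants centred on the pure positions: LEFT
[−45, 45), SUPINE [45, 135), RIGHT [135, 180] ∪ (−180, −135), PRONE
[−135, −45), all half-open and configurable in `classify_position()`.
Laying requires the stand angle to be within 45° of ±90; both near-±180
(standing) and near-0 (headstand — impossible while laying) orientations
classify as STANDING. Per-position angle statistics use the circular mean
and circular standard deviation $\sqrt{-2\ln \bar R}$: right-lateral
angles straddle ±180, where arithmetic moments are wrong. Position-shift
counting debounces runs shorter than 30 s (configurable): the median
filter already suppresses faster flicker, and a dwell guard makes the
count robust to boundary chatter.

## Desaturation detection

An event is a drop of ≥ 3 percentage points (inclusive) below the
preceding baseline, with the nadir reached within 120 s. Neither the
baseline nor the event end is fully specified by that sentence, so the
detector makes both operational:

- Candidate nadirs are local minima lying ≥ 3 points below the running
  maximum of the preceding 120-s window.
- The fall start is the last sample attaining that running maximum,
  refined to the last sample within half a recovery margin of the
  baseline before the nadir — on a noisy plateau the literal argmax can
  sit the better part of a minute before the physiological shoulder,
  which would both leak earlier samples into the event span and (for
  events chained close together) collide with the previous event.
- The baseline value is the running maximum of the 30 s before the fall
  start (standard desaturation-scoring practice; configurable).
- The event ends at recovery to baseline − 1 point, or at the end of the
  series; candidates inside a previous event are merged into it, so one
  long hypoxic episode yields one event, and scanning re-baselines after
  each event so back-to-back dips score separately.

Slow drifts are rejected structurally: a fall spread over 300 s never
accumulates 3 points within any 120-s window. The detector is invariant
to adding a constant to the whole trace. ODI severity uses the 5 / 15 /
30 events-per-hour bands with left-closed intervals (ODI 15.0 is
Moderate), and the ODI denominator is laying time when an angle series is
linked, otherwise total recording time. A pre-scored vendor event list
can be supplied in place of the detector (`analyze_night(events = ...)`).

## Angle-resolved profiles

All four per-degree statistics share one counting primitive: the number
of angles within 7.5° (inclusive, circular) of each integer grid angle
−180…179 (+180 aliases −180). Each sample therefore falls in exactly 15
windows, giving the conservation law $\sum_\theta \%\mathrm{Position} =
1500$ used as a test invariant. The counting is implemented as a
difference array over a doubled grid, exactly equal to the naive double
loop at any window width.

The local ODI normalises window event counts by window occupancy in
hours (samples / 36,000 at 10 Hz; derived from the actual sampling rate
otherwise). Two guards suppress small-denominator artifacts: occupancy is
floored at 10 minutes for the local ODI and at 1% for the %DE/%Position
ratio; angles with zero occupancy are masked outright. The clamp is
applied before the circular 5-point moving-average smoothing, and masked
cells are excluded from their neighbours' averages (the alternative
order, smoothing before clamping, is available via
`analysis_config(smooth = FALSE)` plus manual smoothing, but the default
follows the order in which the quantities are defined). Event angles are
the circular mean of the sleep angles spanning the event; a circular
median is available (`statistic = "median"`) since the procedure is
described both ways in the field. Note that clamped cells are biased low
by construction — analyses that want unbiased per-angle rates (e.g. the
parameter-recovery checks in the test suite) should restrict to cells
with ≥ 10 minutes of occupancy, which the profile exposes via its
`hours` column.

The normalisation constant deserves a note: written as a single literal
it can be misread as 136,000, which would put the local ODI nine orders
of magnitude below the 0–100 h⁻¹ range on which it is interpreted; it is
1/36,000 — samples per hour at 10 Hz — and is exposed in
`analysis_config()`.

## Vibration treatment

While the classified position is SUPINE (and not STANDING), pulses of
300 ms fire every 3 s, starting immediately on entering supine (a
`grace` delay is available) and strictly within the supine run. The
"supine-like" band is identical to the SUPINE classification quadrant and
configurable with it.

## The synthetic generator

`simulate_night()` produces the stated world every test runs against:

- **Positions.** A semi-Markov chain over position labels with log-normal
  dwells (default ~25 min) and a transition matrix biased through supine,
  matching how sleepers roll. Default centres (left 30°, supine 90°,
  right 160°, prone −100°) sit near pooled per-position means reported
  for sternum-worn devices; per-bout angles are von Mises draws
  (σ = 6°) around them. One ~2-min standing interruption is inserted by
  default.
- **Calibration bout.** Every night opens with a supine bout of ≥ 12 min
  so the calibration assumption holds. The settling bout's angle uses a
  smaller jitter (σ = 2°) than mid-sleep bouts: calibration rests on the
  wearer deliberately lying flat, a more stereotyped posture than
  whatever they roll into asleep. Because the offset is only identifiable
  up to this anchor, ground truth reports angles and labels in both the
  planted and the calibrated frame, and recovery tests compare against
  the calibrated frame.
- **Accelerometry.** The angle formula inverted: gravity (cos φ, 0,
  sin φ) g for sleep angle φ while laying, a −Y-dominant vector while
  standing, plus white noise (σ = 0.02 g) and ±20 ms uniform timestamp
  jitter on the nominal 10 Hz grid.
- **SpO2.** 1 Hz, baseline 97% with AR(1) noise (marginal σ = 0.3%), and
  trapezoidal desaturation dips: descent 20–90 s, plateau 0–20 s,
  recovery 10–60 s, depth 4–8 points. Events form a hard-core renewal
  process per laying bout — cycle = dip duration + exponential gap with
  the gap mean set so the mean cycle is 1/rate — so the nominal
  events-per-hour rate is also the realized rate while successive dips
  stay ≥ 5 s apart and individually scorable. Independent Poisson onsets
  cannot deliver that: at 40/h the dips alone would occupy more than the
  hour, and thinning collisions silently cut the realized rate by a
  third. High-rate scenarios (the 40/h recovery model, the 45/h severe
  cohort band) use shorter dips (descent 15–45 s, plateau 0–10 s,
  recovery 10–30 s), the fast periodic cycling typical of severe OSA;
  rates that fit the default shape keep it.
- **Treatment.** Under vibration the wearer leaves supine after a
  geometric number of whole vibration-minutes (success probability =
  `compliance`, default 0.9) plus a uniform settling fraction; the
  opening calibration window is exempt, after which the clock starts.
  Transitions out of a truncated bout follow the same matrix.

What the generator does **not** emulate: dynamic (non-gravity)
acceleration, within-bout postural drift, oximeter quantisation and
dropouts, pulse-rate physiology, apneas without desaturation, and any
coupling between position changes and arousals. A green test therefore
establishes that the pipeline recovers what this model plants — angles,
labels, event times, rates — not that it would be equally accurate
against polysomnography.

Default scenario parameters were chosen once: the default subject plants
25/h supine vs 5/h lateral (a clearly positional, moderate night); the
recovery scenario plants 40/h vs 5/h with supine occupancy near a third
of the night so the supine ratio stays interpretable; the four-subject
cohort spans the severity bands at roughly 1, 8, 20 and 45 events/h.

## Numerical choices and degenerate inputs

- Angle wrapping always lands on (−180, 180]; −180 is mapped to +180.
- `sign(0) = +1` in the orientation formula.
- The 2-minute validity threshold is inclusive (exactly 120 s is kept).
- Depth comparison in the detector is inclusive (exactly 3.0 points
  qualifies).
- Low-res export picks the nearest filtered sample on the 5-s grid
  spanning [0, duration]; no anti-alias filter, as the series only feeds
  plots.
- Zero laying time makes position percentages undefined (`NA` with a
  warning), not zero.
- Calibration on a recording shorter than its window falls back to zero
  offsets with a warning.
- Events overlapping no angle samples are dropped from the profile with
  a warning.

## Limitations

The discrete boundaries (±45°, ±135°) are a convention, not a fit;
published per-subject tables show lateral means (e.g. 125.5°) that a
different device placement can push across them, which is why the
boundaries, the laying threshold and the window width are all arguments
rather than constants. ODI understates apnea-hypopnea burden whenever
apneas occur without a ≥ 3% desaturation. The ratio profile becomes
unstable for subjects with very few events, and the local ODI cannot
say anything about angles a subject never slept at — both masks exist
precisely to keep those cells visibly absent rather than silently zero.
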