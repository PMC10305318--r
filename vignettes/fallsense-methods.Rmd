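---
title: "Methods: chest-worn IMU fall recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chest-worn IMU fall recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsense)
```

## Overview

`fallsense` implements a threshold-based fall recognition pipeline for a
chest-worn device carrying a 100 Hz nine-axis IMU and a barometric
altimeter, together with the surrounding machinery needed to make such a
pipeline testable on a desk: a seeded kinematic simulator, a behavior state
machine, two-stage alert verification, and evaluation utilities. This
vignette documents the model, the defaults, the numerical choices, and the
limits of what the synthetic experiments demonstrate.

## Signal model and device frame

The device frame is **+X wearer's right, +Y anterior (out of the chest),
+Z superior**; the earth frame has +Z up. At quiet upright stance the
accelerometer reads $(0, 0, 1)$ g. Lean angles are defined directly from
the gravity direction in the body frame: a forward lean makes **pitch**
positive, a right lean makes **roll** positive, and both are zero upright.
This is the one frame in which three requirements coincide naturally: the
identity quaternion is the upright posture, the accelerometer equilibrium
is the +Z axis, and the fall-direction sign rules (forward/backward from
pitch, left/right from roll) need no extra remapping.

The per-sample resultant G value is the Euclidean norm of the three
acceleration axes. It is unit-agnostic: the detector converts g to raw
accelerometer counts with the 512 LSB/g sensitivity of the reference
hardware, whose operating ranges (±4 g, 300–1100 hPa) are also the
validation bounds for sensor logs.

## Orientation: gradient-descent fusion

Orientation is tracked with the Madgwick gradient-descent filter. Each step
integrates the gyroscope quaternion rate and subtracts `beta` times the
normalized gradient of the accelerometer objective (the magnetometer term
is added when a magnetic field is present), then renormalizes; a zero-norm
accelerometer sample degrades that step to flagged gyro-only integration.
The filter gain **`beta` defaults to 0.1** (dimensionless): at 100 Hz this
pulls integration drift back to the accelerometer vertical within a couple
of seconds while remaining insensitive to short linear-acceleration
transients. The inner loop is compiled (Rcpp); an R single-step
(`madgwick_update`) exposes the same computation for stepwise use, and the
tests pin both against closed-form oracles (static-tilt `atan2` recovery,
pure gyro integration) and against each other.

Euler extraction uses a yaw–pitch–roll decomposition (yaw about earth Z,
pitch about the body lateral axis, roll about the body anterior axis) whose
gimbal singularity sits at |pitch| = 90°. Within 0.1° of it the pitch is
clamped and flagged. The simulator's falls settle at 60–80° lean, so the
pipeline operates away from the singularity; sideways falls load the roll
axis, whose extraction has no singularity at 90° roll.

## Altitude: hypsometric conversion and Kalman smoothing

Pressure maps to relative altitude by the standard-atmosphere hypsometric
formula (sea level 288.15 K, lapse 6.5 K/km), about +1 m per −12 Pa near
sea level; the reference pressure is the median of the first half second of
each trace. A scalar random-walk Kalman filter smooths the altitude, with
defaults **`q_proc = 1e-4` m² per sample** and **`r_meas = 0.25` m²**. The
measurement noise is not a free parameter: 0.25 m² is exactly the
altitude-equivalent variance of the barometer's 6 Pa noise floor
(6 Pa ÷ ~12 Pa/m ≈ 0.5 m). This pair gives a steady-state gain near 0.02
per sample, i.e. a ~0.5 s time constant — strong enough to bring the
residual altitude noise to ~0.05 m (so the 3 Pa decision threshold and the
0.2 m chair band are meaningful), short enough that a 1.5 s sit-down or a
0.5 s fall drop still registers inside its decision window.

Consequently the "pressure difference" consumed by the detector and the
state machine is computed on the **filtered** barometric signal mapped back
through the hypsometric relation, not on raw samples: the raw noise floor
(σ ≈ 6 Pa) would swamp a 3 Pa threshold entirely, and smoothing the
relative altitude before observing its change is precisely the role of the
Kalman stage in this design.

## Decision features and the fall rule

Features are evaluated every **0.1 s** (the sensor read cadence):

* `dg_window` — max − min of the resultant G over the trailing **1.0 s**.
  The range statistic sees the weightless dip and the impact peak as one
  number. The G window is a package choice: it must cover dip-plus-impact
  (~0.4 s) with margin while keeping the detector responsive.
* `dp_window` — absolute change of the filtered barometric signal over the
  trailing **1.5 s**, the altimeter observation window used for behavior
  decisions.

The fall rule is the strict conjunction **`dg > 600` LSB and `dp > 3` Pa**.
The thresholds are interpreted physically: 600 counts ≈ 1.17 g of G range,
and 3 Pa ≈ 0.25 m of altitude change — the only reading of those two
numbers under which both quantities are simultaneously plausible for a
chest-height fall (a ~1 m chest drop is ~12 Pa) yet above normal-activity
levels (walking G range ~0.45 g ≈ 230 counts; a chair sit-down is ~5 Pa
but only ~200–400 counts). Both are configuration fields. Events are
separated by a **3 s refractory period** so impact bounces are not
double-counted.

Direction is classified from the lean angles **0.5 s after the impact
peak** (the settled lying posture, not the chaotic impact instant) with a
dominant-axis rule and a 20° dead zone below which the direction is flagged
indeterminate; ties between |roll| and |pitch| resolve to the pitch axis.
Impact magnitude is the G maximum between the weightlessness minimum (the
first contiguous dip below 0.6 g) and one second later; a series with no
sub-0.6 g dip yields the whole-window peak, flagged.

## The behavior state machine

A Mealy machine over eight states — INITIAL, STANDING, SITTING, LYING,
WALKING, SITTING_DOWN, STANDING_UP, FALLING — consumes one input label per
tick and only moves along edges of an explicit transition table; an illegal
(state, input) pair leaves the state unchanged and emits nothing, which is
the mechanism that rejects physically impossible jumps such as standing
directly to sitting. The shipped table is plain data (editable, loadable
from CSV); falls are accepted from all five postures the protocols start
from, and self-inputs are implicit no-ops.

The per-tick labels come from threshold rules whose parameters are exposed
in `fallsense_config()$fsm`:

* **lying**: max(|roll|, |pitch|) > 60° sustained for 1 s;
* **sit-down / stand-up**: signed altitude change over the 1.5 s window
  within the chair band **0.2–0.7 m**, persisting for 3 of the trailing
  5 ticks. The 0.2 m lower edge reflects what a 0.45 m chair transition
  looks like *after* Kalman smoothing (attenuated to roughly 0.27–0.35 m
  in the window) while staying ~3σ above the residual noise; the 3-of-5
  persistence keeps a single noise flip at the band edge from breaking the
  run;
* **walking**: at least 3 G-oscillation peaks above 1.15 g in the trailing
  2 s, with the window's G range at most 0.9 g so that impact transients
  are not mistaken for gait;
* anything else is the quiescent upright label (standing-compatible).

Ties resolve by safety priority: FALLING > LYING > SITTING_DOWN /
STANDING_UP > WALKING > STANDING. The machine starts in INITIAL and leaves
it only after ~3 s of detected walking (the wearer's ten calibration
steps); the transient SITTING_DOWN/STANDING_UP states resolve to
SITTING/STANDING after 1 s of quiescence. The pre-fall state attached to an
event is the last non-FALLING state strictly before the impact time; since
transitions triggered by the fall itself occur after the impact instant,
this lookup is robust to transient mislabels during the fall.

## Alert verification

Verification is pure event/timer logic with an injected clock and a
pluggable notifier, so action logs are exactly reproducible. A detected
fall creates a PENDING record and one first-stage notification; at the
**30 s** deadline the record is CONFIRMED with a second-stage escalation iff
the current behavior state is still FALLING or LYING — a fallen wearer who
has not gotten up is lying, so "still fallen" is read from the state
machine rather than from a raw re-detection — and auto-resolves as
CANCELLED otherwise. The wearer may cancel strictly before the deadline;
cancelling afterwards is an error because the escalation decision has
already been taken. Each fall therefore produces exactly one or two
notifications.

## The synthetic-trace generator

No public recordings exist for this protocol family, so the package ships a
generator that emulates the test protocols: category A (fall starting from
sitting), B (fall while standing), C (fall while standing up), each in four
directions, plus matched ADL negatives (normal and fast sit-downs for A,
walking and deliberate lying-down for B, normal and fast stand-ups for C).
Each script is a sequence of kinematic segments prescribing the true lean
trajectory, chest altitude and G-magnitude profile; the sampled signals are
derived from those (accelerometer = magnitude × body-frame gravity
direction, gyroscope = exact body rates of the quaternion trajectory,
barometer = hypsometric pressure of the altitude), so labels and kinematics
cannot disagree. Gaussian noise at the reference hardware's levels is then
added: **σ = 0.01 g per accelerometer axis, 0.5 °/s per gyro axis, 6 Pa of
pressure**.

Fall kinematics default to physiologically plausible magnitudes chosen once:
weightless dip to 0.2–0.5 g, impact peak 2.4–3.6 g, settled lean 60–80°,
chest drop 1.1–1.3 m from standing, 0.8–1.1 m from mid-rise, 0.6–0.8 m from
sitting; chair height 0.45 m over 1.5 s; walking at 2 Hz with G peaks
~1.3 g. All are configuration fields, deliberately straddling the detector
thresholds so borderline behavior is testable (the fast sit-down, for
example, produces ~0.7 g of G range and ~5 Pa — above the pressure
threshold, below the G threshold).

**What passing tests do and do not show.** The generator produces clean
single-axis falls with idealized weightlessness and impact shapes,
stationary pressure apart from posture changes, no soft-tissue dynamics, no
stumbles/recoveries, no sensor drift or mounting misalignment, and noise
that is Gaussian and white. Perfect or near-perfect metrics on this grid
demonstrate that the pipeline implements its stated rules correctly and
that the thresholds are mutually consistent with the assumed kinematics —
not that the detector would reach those numbers on real falls of real
subjects. The per-category evaluation at `n_per_cell = 50` (600 fall trials
plus 600 matched negatives, the scale used by `scripts/acceptance.R` and
the acceptance test) was sized to estimate per-category rates from 400
trials each.

## Numerical and degenerate-input choices

* Quaternions are renormalized every step; norm drift stays below 1e-9
  over 10⁵ updates (tested).
* Kalman updates skip (and flag) non-finite measurements; estimates are
  convex combinations of prior and measurement by construction.
* Windows that would extend before the start of a trace are truncated and
  the frames flagged; traces that end before initialization return an
  all-INITIAL timeline with a warning.
* Zero denominators in sensitivity/specificity/accuracy yield `NA`, never 0.
* CSV round trips preserve values to at least 6 significant digits
  (written at 10); timestamps are seconds from trace start, since the
  pipeline needs only time differences.
* Per-trial seeds are drawn once from the master seed, so experiment
  collections are reproducible as a whole and trials individually.

## Known limitations

Yaw is unobservable without a magnetometer and is not used by any decision.
The direction classifier assumes the settled posture is reached within
0.5 s of impact. The chair band assumes roughly chair-height furniture; the
walking detector assumes near-2 Hz cadence. Thresholds are global, not
per-user calibrated. The alert module implements timer/cancel logic only;
delivery infrastructure is out of scope by design.
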