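---
title: "Abstract myoelectric control and personalized decision boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstract myoelectric control and personalized decision boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstractmyo)
```

## The control problem

A multi-grasp prosthetic hand needs a way for its user to select among
several grasps using only a couple of surface EMG channels. Abstract
myoelectric control sidesteps pattern recognition over many electrodes:
the user learns an arbitrary mapping in which the smoothed activity of
two forearm muscles (by default labelled FCR and ECR) drives a cursor in
the first quadrant of a 2D task space. Co-contraction patterns place the
cursor at an angle; four targets arranged on a ring each carry a grasp
(power; tripod or pinch; point; hand open). Reaching a target and holding
the cursor there selects the grasp.

Because the feature that ultimately decides *which* grasp runs is a single
angle, the decision rule is one-dimensional and can be personalized from
real-life usage data: each user drifts toward their own comfortable
co-contraction angles, and the decision boundaries can be refit to follow
them. This package implements the whole loop offline — signal chain,
decoder, session logging with user feedback, boundary adaptation — plus a
virtual user so that everything is testable without human or hardware
data.

## Signal chain

Raw EMG is sampled at 500 Hz per channel. Preprocessing is a 4th-order
Butterworth bandpass plus a biquad mains notch:

* **Passband 20–230 Hz.** 20 Hz removes motion artefact and baseline
  drift; 230 Hz leaves a margin below the 250 Hz Nyquist limit. These
  edges are explicit package defaults in `filter_spec()`, chosen as
  typical surface-EMG conditioning values, and are config-overridable.
* **Notch 50 Hz, Q = 30.** Mains interference sits inside the passband,
  so it is removed separately.
* Filtering is zero-phase (forward–backward) by default, which is the
  right choice for offline analysis; `zero_phase = FALSE` gives the
  causal single-pass variant when closed-loop latency realism matters.

The control feature is the mean-absolute value (MAV): the mean of the
rectified signal over a trailing window, by default 150 ms long with a
50 ms step. The window is deliberately a device setting — it trades
smoothness against control latency, and 150/50 ms is a conventional
myocontrol latency budget.

Calibration maps raw MAV to normalized units: the rest level is the
*median* MAV of a relaxed recording and the maximum level is the *95th
percentile* of the MAV during a maximum voluntary contraction, both
chosen for robustness against transient spikes. `normalize_mav()` floors
at the rest level, scales the calibrated range to `[0, 1]`, applies a
per-channel gain, and clips at `m_cap = 1.5` so that overshoot beyond the
calibrated maximum remains representable but bounded.

## Decoder geometry and semantics

The four target centres default to the bisectors of the four default
decision regions — 11.25°, 33.75°, 56.25°, 78.75° — on a ring of radius
0.7 in normalized MAV units. The target disc radius defaults to 0.12:
this is the largest round value for which adjacent discs are disjoint
(adjacent centres are `2·0.7·sin(11.25°) ≈ 0.273` apart) and for which
each disc's angular span (`±asin(0.12/0.7) ≈ ±9.9°`) stays inside its
own 22.5°-wide decision region. The rest basket is the disc of radius
0.15 around the origin.

Selection is by dwell: a target fires when the cursor stays inside its
disc continuously for `dwell_ms` (default 500 ms — a common dwell
compromise between speed and false selections; the study protocol leaves
it as a free device setting). Leaving the disc resets the timer, and a
fired target is latched until the cursor leaves, so one visit fires at
most once.

The *executed* target of a command is not the disc but the angular
decision region containing the decision angle `v` at dwell completion,
under the boundaries in force at that moment. With the default geometry
the two coincide, because each disc sits inside its region; once
boundaries are customized, the region decides. This is what makes a
boundary update — including one applied mid-session through
`boundary_updates` — change behaviour, and it mirrors how customized
boundaries are deployed to the controller in practice. The decision
angle is taken at dwell completion rather than dwell onset, matching the
convention that the logged "decision point" is the moment the command
is issued.

Angles are classified with half-open intervals (`v < b12 → 1`,
`b12 ≤ v < b23 → 2`, …): a boundary angle belongs to the higher-indexed
target. The same tie-break is used everywhere, including adaptation
evaluation.

The hand state machine removes inadvertent grasps: a closing command
(targets 1–3) is accepted only when the hand is open *and* the cursor
has re-armed by visiting the rest basket since the hand last opened; an
open command (target 4) is accepted only when the hand is closed.
Ineligible fires are logged as discarded events rather than dropped
silently, since whether the original system recorded them is not
something the package can know; keeping them costs nothing and aids QC.

Familiarization trials use stage-1 semantics: the prompted target's disc
must be *entered* (no dwell) within 1.5 s, and a familiarization stage is
cleared when every target's success rate exceeds 70%.

## Session log and feedback labeling

The session bucket stores individually time-ordered streams: MAV
samples, motor commands, user feedback, discarded fires, configuration
updates, and block markers. Timestamps serialize as ISO-8601 UTC with
millisecond precision; values round-trip losslessly through the CSV and
NDJSON dialects (ARFF is a write-only flat relation of commands).

Each feedback event labels the most recent *unlabeled* motor command
that precedes it, marking that command as an unexpected grasp with the
reported intended grip. No time bound is imposed on the link — the
labeling rule is purely "previous command" — but links longer than a
configurable QC lag (default 60 s) raise a warning, because in practice
feedback arrives within seconds. Feedback with no eligible preceding
command is retained as an orphan with a warning. Labeling recomputes all
links from scratch, which makes it idempotent.

Commands without an unexpected-grasp label are the *training* set;
labeled commands are the *verification* set. The two always partition
the command list, which is the accounting precondition behind the
feedback/correction report.

## Boundary adaptation

For each target the decision angles of its correct commands are fit with
a Gaussian (sample mean; sample SD with the n−1 denominator; SD floored
at 0.5° so a cluster of identical angles cannot produce a degenerate
spike). Each adjacent pair of targets then forms a 2-class Naive Bayes
problem in the single feature `v`, and the customized boundary is the
angle where the two weighted class densities are equal:

* Equal variances give the linear solution; with equal priors it is the
  midpoint of the means, which is exactly why the symmetric default
  geometry yields 22.5°, 45°, 67.5°.
* Unequal variances give a quadratic; the root inside `(μᵢ, μⱼ)` is
  taken. If no real root lies between the means (a pathological variance
  ratio), the midpoint is used with a warning.
* The result is clamped to the open interval between the means.

Priors are equal by default: the adaptation rule is phrased in terms of
equal probability *density* between the two targets, which reads as
class-conditional equality, not posterior equality; `priors_mode =
"empirical"` is available for count-weighted boundaries. Per-class
variances are fit separately rather than pooled. Angles are treated as
plain numbers on `[0, 90]` — the quadrant is bounded far from any
wraparound, so circular statistics would add nothing.

A pair with fewer than two training decisions keeps its default
boundary and is flagged; if the adapted triple ever violates
`0 < b12 < b23 < b34 < 90`, the defaults are restored wholesale with all
pairs flagged. Verification reclassifies the unexpected decisions under
the new boundaries; a *correction* is one whose angle now lands in its
intended target. By construction `0 ≤ corrections ≤ feedback`.

## What the virtual user emulates — and what it does not

The simulator exists so the full pipeline can be validated end to end:

* **Aiming** is Gaussian in angle, one draw per reach, with per-sample
  positional tremor (default SD 0.01 task-space units). A Gaussian on
  the linear angle (rather than a von Mises distribution) keeps the
  generative model consistent with the adaptation model; on a quadrant
  bounded away from wraparound the difference is negligible.
* **Mis-aims** occur with a per-reach probability; the mis-aimed angle
  is drawn from the intended target's aim distribution truncated to a
  neighbouring decision region, modelling systematic plus random aiming
  error. Mis-aimed reaches that fire produce exactly the
  unexpected-grasp feedback events that drive adaptation; feedback
  latency is uniform 1–5 s, safely below the 60 s QC lag.
* **Sessions** follow the pick-and-place protocol: 16 blocks in two
  groups of eight, grasp order point/tripod/power/point switching to
  point/pinch/power/point, with the tripod→pinch reconfiguration logged
  between blocks 8 and 9. Every reach runs through the real decoder and
  state machine; a wrong grasp triggers feedback, re-opening, and a
  retry, so blocks contain four objects plus extra reaches for misses.
* **EMG synthesis** is band-limited (20–230 Hz) Gaussian noise scaled to
  unit SD, amplitude-modulated by the commanded activation envelope,
  plus a 50 Hz mains component and white sensor noise. The MAV of such a
  signal is the envelope scaled by `E|N(0,1)| = √(2/π)`, which is the
  analytic ground truth the signal-chain tests check against.

The simulator does **not** model motor-unit physiology, limb-position
effects, fatigue, or learning within a session. Passing tests therefore
demonstrate that the pipeline recovers the parameters of its own
generative model under realistic noise — they do not certify performance
on human data, whose aim distributions may be skewed, multimodal, or
drifting.

## Numerical and reproducibility choices

* Timestamps are rounded to the millisecond before formatting, so
  write→read→write serialization is byte-stable; numeric payloads are
  written with 17 significant digits (parse-exact for doubles).
* All simulator randomness flows through R's RNG; a profile seed makes
  whole sessions reproducible byte-for-byte after serialization. Ground
  truth is returned out of band and never written into the bucket, so
  downstream analysis cannot accidentally peek.
* Validation problem sizes: boundary recovery uses 500 decisions per
  target with 5° aim SD (recovering the symmetric defaults to within
  1°, and shifted boundaries to within 1.5°); the property batteries
  use a 0.1° classification grid, 1000 random mean/SD pairs against a
  bisection oracle at 1e−6, and 10⁴ random fire sequences for the
  state-machine gating invariant. These sizes make the checks sharp
  while keeping the whole suite comfortably fast on a laptop.

## Known limitations

* The calibration routine (rest median, 95th-percentile contraction) is
  a reasonable standard protocol, but it is a package choice: the
  clinical calibration procedure it stands in for is not fully specified
  in the public record of the system this package models.
* The exact filter passband of the original controller is likewise not
  public; 20–230 Hz is a defensible default, not a reproduction.
* Whether the deployed classifier used empirical priors cannot be
  decided from boundary tables alone; the package defaults to equal
  priors and exposes the alternative.
* The open command is dwell-gated like any other target; if the original
  interface gated it differently when the hand was closed, retiming
  would be needed for faithful replay of deposited data.
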