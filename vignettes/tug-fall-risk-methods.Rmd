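---
title: "Methods: simulating and analysing instrumented TUG tests for fall-risk screening"
author: "tugfall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing instrumented TUG tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugfall)
```

## The problem

The Timed Up and Go (TUG) test — rise from a chair, walk 3 m, turn 180°,
walk back, sit down — is a standard mobility screen for older adults.
Instrumenting it with a lumbar-worn inertial measurement unit (IMU) and a
depth camera turns a stopwatch test into a rich kinematic recording: the
IMU yields tri-axial acceleration (vertical V, mediolateral ML,
anterior-posterior AP) and angular velocity (yaw, pitch, roll about those
axes), and the camera yields 25 three-dimensional skeletal key points per
frame. `tugfall` implements the full analysis chain used to ask which of
the parameters extractable from such a recording discriminate
high-fall-risk from low-fall-risk community-dwelling older adults, where
risk groups are defined by a Berg Balance Scale (BBS) cutoff: low risk iff
BBS > 50 (BBS is scored 0–56).

Because no public recording set exists for this protocol, the package is
organised around a synthetic-data module that is itself first-class,
tested code: it generates cohorts whose gait contrasts equal the published
two-group summaries, so every downstream stage can be validated by
parameter recovery rather than against unavailable raw data.

## The synthetic trial model

A trial is a phase-templated composition on one clock:

    sit | sit-to-stand | walk forward | turn | walk back | turn-to-sit | sit

Phase durations, step length/width/duration, turn yaw peaks, knee angles
and walking pitch RMS are drawn per subject from the cohort's
`gait_profile()` (truncated normal draws). The gyroscope channels are
piecewise-smooth parametric curves: raised-cosine-edged (Tukey-like)
pulses for the sit-to-stand and turn-to-sit pitch bursts and for the two
yaw turn pulses, sinusoidal gait-cycle oscillations while walking, plus
white Gaussian noise truncated at ±3 SD. Design choices that matter:

* **Pulse edges are steep (0.4 s raised-cosine ramps), tops are rounded.**
  Steep edges keep the smoothed signal's threshold crossings within one
  sample of the true phase boundary, which is what makes segmentation
  validation meaningful; the small central bump (15 % of the peak) means
  the sample maximum equals the nominal sampled peak at a single point, so
  additive noise inflates the measured "Max" features by ≲1.5 deg/s
  instead of the ~5 deg/s a flat-topped pulse would suffer.
* **Noise is truncated at ±3 SD.** Quiescent sitting baselines then stay
  strictly inside the segmenter's activity floor, and no noise excursion
  can mimic a movement burst. The truncation changes the noise SD by <3 %.
* **The walking distance is exactly 3 m each way**, so the 6 m numerator
  of the step-length definition (6 m / step count) is exact. The step
  count is `round(6 / sampled step length)`; the induced bias on the
  realized step length is below 0.001 m.
* **The turn pitch offset** (the signed pelvic-drift signature: +2.10
  deg/s median for the low-risk profile, −2.80 for the high-risk profile)
  is applied as a plateau whose ramps lie just *outside* the turn
  interval, so the median over the detected turn sees only the full
  offset. It is a per-profile constant, not a per-subject draw: the
  published medians describe the group centre, and a constant keeps the
  sign contrast (the tested property) reproducible in ≥90 % of trials at
  default noise.
* **Skeleton geometry is posed, not simulated biomechanically.** Ankles
  carry the sampled step width exactly (lateral positions ±width/2) and an
  AP separation `L sin(π · step phase)` whose extrema are the step events;
  knees are placed on the hip–ankle perpendicular bisector at the exact
  sampled knee angle; all non-leg joints are rigid offsets from the pelvis
  plus noise, because no extracted parameter reads them.

Defaults are the published cohort values wherever printed (step length
0.37/0.31 ± 0.07/0.06 m; step width 0.13/0.16 ± 0.03 m; turn-to-sit peak
yaw 161.28/122.25 ± 44.40/33.24 deg/s; walking knee angle 158.95/162.18°;
walking pitch RMS 8.16/6.64 deg/s; ages 77.38 ± 5.34 / 82.00 ± 7.36 years
truncated at 65; assistance probabilities 4/26 and 10/15; IMU at 5 Hz).
Where nothing is printed we chose once what is realistic for older adults
and did not revisit: step duration 0.33/0.40 ± 0.03/0.04 s (walking speeds
≈1.1/0.8 m/s, which also reproduces the published walking
percentage-of-duration of ≈39/43 %), sit-to-stand 2.0/2.4 s, turn 2.2/2.6
s, turn-to-sit 3.2/3.6 s, first-turn peak yaw 165/140 deg/s, gyro noise 2
deg/s, accelerometer noise 0.01 units, skeleton at 30 Hz (Kinect v2
convention) with 5 mm joint noise. One trial is emitted per subject; the
protocol implies a single TUG per participant and no within-subject
repeat variance is published.

**Accelerometer scale.** The vertical axis idles at 1.0 sensor units
(gravity-inclusive, g-like) because the published turn-to-sit maxima
(1.14/1.19, labelled m/s²) are only consistent with a g-normalised scale.
The unit label is reproduced; the magnitudes follow the printed numbers.

### What a green test does and does not establish

The generator reproduces every qualitative feature the segmenter relies
on and the quantitative contrasts the statistics are tested against. It
does **not** model soft-tissue artefact, sensor drift, camera occlusion,
multi-step compensatory turns, walking-aid use during the test, or
left/right asymmetry. A green recovery test therefore establishes that the
pipeline is unbiased and calibrated on data of the stated structure — not
that it would perform identically on real recordings.

## Segmentation

The five subtasks are found from the gyroscope only, following the
standard principles: sitting is quiescent, pitch bursts at the transfers,
yaw peaks at the turns, walking is quiet on both axes.

1. Each channel is smoothed with a centered 0.6 s moving average; the
   combined speed √(yaw² + pitch²) is compared against an activity
   threshold `baseline mean + 4 × baseline SD` estimated from the first
   1 s of sitting. The baseline statistics use the *raw* speed: at 5 Hz
   the baseline window holds ~5 samples and the smoothed series grossly
   understates the noise SD, which made thresholds collapse in early
   validation. A supra-threshold run must last ≥0.4 s *and* reach 2× the
   threshold at its peak — the second condition rejects grazing noise
   excursions and costs nothing because genuine bursts exceed it by an
   order of magnitude. Both conditions are relative, so segmentation is
   invariant to rescaling the gyro channels.
2. Within the bounds, the two largest smoothed |yaw| peaks anchor, in time
   order, the turn and the turn-to-sit; each event extends over the region
   where smoothed |yaw| > 0.2 × its peak. Sit-to-stand ends where the
   initial pitch burst falls below 0.2 × its own peak. Equal peaks break
   by earlier time. Crossing times are linearly interpolated between
   samples, so boundaries are continuous times rather than grid points.
3. Intervals are half-open `[start, end)` and contiguous by construction,
   which guarantees the partition identity (the five durations sum exactly
   to the TUG duration) and gives every sample exactly one subtask.

At the 5 Hz default, all boundaries land within ±1 sample period of the
generator's ground truth in ≈96–97 % of trials; residual misses are
threshold-crossing jitter on the shallow pulse edges, not systematic bias.

## Features

The 142-parameter vector follows the published layout exactly: 8 temporal
(duration and percentage-of-duration, POD, for sit-to-stand, merged walk,
turn, turn-to-sit), 66 acceleration (per-subtask statistic sets on each of
V/ML/AP), 54 angular velocity, 10 key-point (legs angle and both knee
angles for walk and turn; step count/length/duration/width), the TUG
duration, and 3 demographics (age; gender M=1/F=0; assistance yes=1/no=0,
the coding that reproduces the published effect size d = 1.236 and odds
ratio 11.000). Conventions that needed a decision:

* **CV is signed** (sample SD over mean, n−1 denominator): the published
  table prints negative CVs. A zero mean yields a missing value with a
  warning rather than an infinity.
* **"Jerk" is the successive absolute difference of acceleration samples**
  in the acceleration unit — not divided by Δt — matching the published
  units; `jerk_stats(per_second = TRUE)` gives the true derivative.
* **The walking phase merges the two walking segments**: durations add,
  and per-sample statistics pool the concatenated samples.
* **Step detection** (unspecified in the source): local extrema of the
  signed AP ankle separation (joint 14 minus joint 18), prominence
  ≥0.05 m, spacing ≥0.3 s; each maximum and each minimum is one step.
  Ankles rather than feet carry step width (configurable), and the axis
  mapping is a parameter for non-simulated data.
* **Knee/legs angle phase features are frame-wise means** over the phase;
  angles are computed from the joint vectors (right knee: angle at joint
  17 between 17→16 and 17→18; legs: between 0→17 and 0→13) and live in
  [0°, 180°].

## Statistics

Per parameter, a Shapiro–Wilk test (α = 0.05) within each group gates a
pooled-variance two-sided t-test (both groups normal) versus a two-sided
Mann–Whitney U with tie correction; binary 0/1 parameters go to Fisher's
exact test. Effect size is Cohen's d with the (n−1)-weighted pooled SD,
reported as a magnitude — the only variant that reproduces the published
0.752 (age), 1.236 (assistance) and 0.630 (turn-to-sit yaw RMS) from their
printed summaries. The screen keeps parameters with p < 0.05 and d
strictly > 0.8, ordered by p. No multiplicity correction is applied by
default (matching the source analysis); a Benjamini–Hochberg option
exists. Logistic regressions are plain ML fits with Wald 95 % CIs; the
published lower CI bound for assistance (2.619) is not a Wald bound
(Wald gives ≈2.42) and is deliberately not targeted. AUC uses the
rank-sum formulation (ties ½), which equals Mann–Whitney U / (n₁n₂), and
the ablation compares in-sample AUCs of the three published feature sets
(IMU: turn-to-sit peak yaw, yaw CV, peak V acceleration; depth camera:
step length, step width; combined). In-sample evaluation matches the
source procedure; note that under label permutation the in-sample AUC of a
refit model concentrates near 0.5 *plus* the usual optimism (≈0.65 at
n = 41 with 3–5 predictors), so chance-level behaviour is verified with
fixed scores against permuted labels, where 0.5 is exact.

Separation and collinearity are refused explicitly: a rank-deficient
design raises a collinearity error before fitting, and a fit whose
deviance vanishes (complete separation) raises a separation error.
Coefficient magnitude is *not* used as a separation criterion — meter-
scaled gait predictors legitimately carry slopes around 30.

## Numerical and degenerate-input policy

Tolerances in tests are exact-to-floating-point for algebraic identities
(partition of durations, oracle comparisons) and 2-standard-error bands
for Monte-Carlo recovery. Degenerate inputs fail loudly with classed
errors: non-monotone time axes and non-finite values name the offending
row/column; all-quiet recordings are "no TUG detected"; activity touching
the file edge is "no pre/post baseline"; a missing yaw peak is "turn not
found". Subjects with missing sensor files are excluded with one warning
each, never silently.

## Known limitations

The 2-SE recovery checks are one-sample t-tests against the generating
means: each has the nominal ~5 % false-alarm rate from the cohort draw
itself, so a ten-row recovery table fails somewhere in roughly a third of
seeds even for a perfect pipeline. Similarly, requiring the three
headline parameters (step length, step width, turn-to-sit peak yaw) to
*jointly* clear the d > 0.8 screen at n = 100/100 has success probability
≈0.75–0.85 under the published SDs (true d ≈ 0.9–1.0, sampling SD of d ≈
0.15): a ≥90 % joint-selection rate would require larger true effects
than the publication reports, so that acceptance check can fail honestly
— the per-parameter selection rates and the recovered means are the
informative quantities. At 5 Hz a subtask holds 10–20 IMU samples, so
medians and CVs are coarse; this mirrors the modeled hardware, and every
stage accepts higher rates.
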