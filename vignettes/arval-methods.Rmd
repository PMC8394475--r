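---
title: "Validating smartphone AR head tracking against optical motion capture: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating smartphone AR head tracking against optical motion capture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arval)
```

## The measurement problem

A smartphone mounted in a passive headset tracks the wearer's head while
they play an augmented-reality exercise game (squats, side-steps, step-ups,
as used in rehabilitation after hip replacement).  The phone reports its
pose at about 30 Hz in its own world frame.  To decide whether this tracking
is accurate enough to quantify exercise amplitude, it is compared against an
optoelectronic motion-capture system recording four reflective markers on
the headset at 120 Hz in the laboratory frame.

The two streams disagree in three uninteresting ways before they disagree in
the interesting one: their clocks are offset, their world frames differ, and
their sampling rates differ.  `arval` removes the first three (synchronization,
frame registration, resampling) and quantifies the fourth with a standard
method-comparison battery.

## Pipeline

For each trial, `run_validation()` executes:

1. **Pose reconstruction** (file-based marker input): position is the
   centroid of the visible markers; orientation is a least-squares rigid
   (Kabsch/SVD) fit of the marker model, decomposed into Euler angles.
   Frames with fewer than three visible markers become gaps; gaps shorter
   than `max_gap` (default 0.2 s) are filled linearly, longer ones are
   excluded from metrics.
2. **Synchronization**: both recordings start with a scripted landmark —
   five head nods.  The lag is the argmax over integer shifts (±3 s by
   default) of the normalized cross-correlation of the mean-removed flexion
   channel, with both streams compared on the training-game time grid (the
   coarser stream, so no detail is invented at 120 Hz), refined to
   sub-sample precision by parabolic interpolation of the correlation peak.
   A peak correlation below 0.5 attaches a low-confidence warning.
3. **Frame registration**: the phone's inertial unit keeps its world frame
   gravity-aligned, so the two frames can differ only by a signed relabeling
   of axes plus a translation.  `align_frames()` picks, among the 48 signed
   permutations, the one maximizing the sum of per-axis correlations, then
   removes per-axis mean offsets.  Rotation channels get a mean-offset
   correction as well (a constant yaw mismatch otherwise contaminates the
   rotation metrics).  An unconstrained Procrustes rotation is available
   behind `free_rotation = TRUE` for devices without gravity alignment.
   If the two best permutations score within 1% the alignment is declared
   ambiguous and the trial errors out rather than guessing.
4. **Trajectory agreement**: per-frame differences on the common grid are
   pooled across trials; each channel reports the mean and sd of the pooled
   absolute differences (MAD ± SD) and the RMSE.  The sd can exceed the
   mean — absolute differences are folded, strongly right-skewed.
5. **Repetitions**: segments are either copied from ground-truth labels
   (synthetic data) or detected on each exercise's primary axis —
   transversal for side-steps, longitudinal for squats and step-ups — as
   contiguous excursions above 10% of the height-scaled threshold whose
   maximum reaches the full threshold.  The repetition amplitude is the
   time-independent range (max − min) of the primary-axis channel in the
   interval.  Repetitions are paired across systems greedily by interval
   overlap within the same exercise label.
6. **Amplitude agreement** per exercise: MAD ± SD, RMSE, MARD
   (mean of |tg − ref| / ref), Spearman's rho with a t-approximation
   p-value, ICC(2,1), Lilliefors-corrected Kolmogorov–Smirnov normality
   p-values, and a non-parametric Bland–Altman summary.

## Statistical conventions

Where the method-comparison literature offers variants, the package pins one
and documents it here:

* **ICC**: two-way random effects, absolute agreement, single measure —
  ICC(2,1) — from the two-way ANOVA mean squares, with the standard F-based
  95% confidence interval and a p-value from F = MSR/MSE.  Treating the two
  systems as random raters is the conservative choice for instrument
  validation, where one asks about agreement, not mere consistency.
* **Normality**: the Kolmogorov–Smirnov statistic with parameters estimated
  from the sample requires the Lilliefors correction; p-values come from a
  seeded Monte-Carlo null table (10^4 replicates per sample size, computed
  once and cached), as `(1 + #{D* ≥ D}) / (reps + 1)`.
* **Bland–Altman**: differences are tg − reference (instrument under test
  minus reference).  Because exercise amplitudes need not be normal, the
  bias is the median difference and the limits of agreement are the 2.5th
  and 97.5th percentiles, with the linear-interpolation (type 7) percentile
  definition — at n near 100–200 the limits are sensitive to this choice,
  so it is fixed and stated.  The parametric mean ± 1.96 sd variant exists
  behind a flag only.
* **Sample size**: the Fisher-z formula
  n = ((z₁₋α/₂ + z₁₋β) / atanh(r))² + 3, *rounded to the nearest integer*.
  The Fisher-z approximation slightly overshoots the exact bivariate-normal
  power calculation (for r = 0.5, α = 0.05, power 0.8 it gives 29.01);
  standard power software reports 29, and rounding — not ceiling —
  reproduces that while staying power-sufficient under the Fisher-z test
  itself for the cases the test suite checks.
* **Euler convention**: intrinsic rotation (about the longitudinal axis) →
  flexion (transversal) → lateral flexion (sagittal).  The channel names
  are standard; the sequence is not dictated by them, so generator and
  analysis share this one convention throughout.

## The synthetic world

`generate_subject()` draws heights from N(1750, 100²) mm truncated to
[1400, 2100] (the study population was 175 ± 10 cm).  The scripted trial is
five synchronization nods, then 3 squats, 3 side-steps right, 3 step-ups,
3 side-steps left; each out-and-back side-step is one repetition, so a
scripted trial holds 3 + 6 + 3 repetitions.  The free-play trial is about
one minute of exercises in random order.

Motion primitives are raised-cosine pulses: smooth (C¹), band-limited, and
with analytically known amplitude, which makes every downstream recovery
testable against exact truth.  Defaults: squat depth 0.20·height, step-up
200 mm, side-step 300 mm, nods 20° with a ±20 mm coupled sagittal
translation (so position-based cross-correlation can also lock on);
repetitions last 3 s.  The two recordings are degraded independently:
sub-millimetre white position noise for the reference (optoelectronic
systems resolve markers below 1 mm), and for the training game a clock lag,
a world-frame rotation and offset, white position noise (default 20 mm) and
rotation noise (default 0.6°), plus an optional linear drift, off by
default because no relevant drift was observed over trials of a few
minutes.

What the generator does *not* emulate: temporally correlated tracker error
(SLAM jitter and drift bursts are smooth, not white), marker occlusion
patterns of real labs, soft-tissue/headset slippage, and any whole-body
kinematics — only the headset trajectory is simulated.  A green synthetic
test therefore establishes that the pipeline recovers what it is supposed
to recover under controlled degradation; it does not certify the instrument
itself.

## Numerical choices and edge cases

* Resampling is linear, with rotation channels unwrapped first so
  interpolation never crosses the ±180° seam; extrapolation is refused.
* The common grid is the training-game timestamps restricted to the overlap.
  When the 30 Hz grid is a subset of the 120 Hz grid, interpolation at
  shared nodes is exact, so a zero-perturbation cohort yields exactly zero
  MAD/RMSE — a useful identity check.
* Lag search window defaults to ±3 s (operators start the systems within
  seconds); the estimate errors out on zero-variance channels.
* Repetition detection uses height-scaled thresholds (squat 0.10·height,
  step-up 0.07, side-step 0.10, minimum duration 0.8 s), chosen so default
  synthetic amplitudes clear them with ≥2× margin.  When detections of
  different exercises overlap in time, the larger threshold-normalized
  excursion wins (deterministic tie-break).  Region-based detection (one
  repetition per contiguous super-threshold excursion) deliberately counts
  a flat step-up plateau once, where naive peak-picking finds several noisy
  local maxima on it.
* The time-independent max − min amplitude is *biased upward* under white
  frame noise: the maximum over the near-flat samples around each extremum
  exceeds a single draw, inflating amplitudes by roughly 3σ at the default
  rates and shapes.  This is a property of the estimator the method
  prescribes, not of the implementation; with temporally correlated (smooth)
  tracker noise the inflation largely disappears.  Consequently per-rep
  amplitude errors under white noise are *not* bounded by ±3σ√2, and the
  test suite documents this honestly rather than smoothing before the
  extremum (which would change the estimator).
* ICC on a single subject's repetitions is near zero by construction —
  within one subject all true amplitudes are equal, so there is no
  between-repetition variance to agree about.  Meaningful ICCs need the
  cohort's height-driven amplitude spread (clearest for squats, whose depth
  scales with height; fixed-displacement exercises have little true spread
  in the synthetic world and correspondingly uninformative ICCs).

## Reporting

The report bundle contains `report.json` (provenance, per-trial sync
results, counts, all tables), position and rotation trajectory tables,
the per-exercise amplitude battery, and per-exercise Bland–Altman
plot-data CSVs (mean, difference, median and limits in a comment header).
Free-play trials contribute to trajectory metrics but are excluded from
amplitude pairing by default (amplitudes are defined by the scripted
protocol); both behaviours are switches on `run_config()`.  A trial whose
stream fails validation — for instance a corrupted recording — is skipped
and listed in the report's exclusions, so a 30-subject study with one
corrupt recording reports 59 analyzed trials.

## Limitations

Exact numeric replication of a specific laboratory's rotation table is
convention-dependent (the marker model coordinates and the reference
software's Euler sequence are not public); the package's conventions are
internally consistent and stated.  Clock drift (linear time-warp) between
the systems is not estimated — over trials of ≤ 2.5 min it is negligible —
and exercise *quality* scoring is explicitly out of scope.
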