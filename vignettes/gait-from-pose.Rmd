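---
title: "Estimating gait variables and fall risk from 2D pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait variables and fall risk from 2D pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gaitvision)
library(dplyr)
```

## The problem

Older adults with dementia fall often, and their gait is hard to assess with
conventional clinic-based tests. A practical alternative is ambient
monitoring: a fixed hallway camera records short walking bouts as residents
pass by, an off-the-shelf 2D pose estimator tracks a small set of body
keypoints in each frame, and gait variables are computed from those keypoint
time series. Because a single camera gives no depth, absolute spatial
measures (step length, walking speed) are out of reach; what *can* be
measured reliably are temporal variables and relative distances normalized
to the person's own body — specifically to the mediolateral *hip span*, the
pixel distance between the left and right hip keypoints. gaitvision
implements that pipeline end to end, from per-frame keypoint JSON to seven
per-bout gait variables, participant baselines, and cohort-level models
linking baseline gait to mobility scores and prospective fall counts.

## Pipeline and model

One walking bout travels through five stages:

1. **Track selection.** A frame may contain several detected people (the
   participant plus accompanying staff). Only one track is analysed. The
   default policy keeps the track with the largest median hip span — the
   foreground person under the camera's perspective — and an explicit track
   id can override it. Selection is deterministic and idempotent.

2. **Confidence gating and imputation** (`threshold_and_impute()`).
   Keypoints with detector confidence strictly below 0.4 are discarded and
   refilled by linear interpolation between the nearest accepted samples;
   edge gaps use the nearest accepted value. The 0.4 default sits at the
   usual trade-off point where few keypoints are lost but unreliable ones
   are removed. Gating is strict at the threshold: a score of exactly 0.4 is
   kept.

3. **Low-pass filtering** (`lowpass()`, `filter_trajectory()`). A
   second-order Butterworth filter with a 4 Hz cutoff — the standard choice
   for gait kinematics sampled at 30 fps — is applied forward and backward
   (zero phase), so foot-strike timing is not delayed; the price is an
   effective doubling of the order, which we accept. Edge transients are
   controlled with odd-reflection padding and steady-state initial
   conditions, giving unit DC gain to machine precision. Filtering runs
   *after* imputation: filtering across unfilled gaps would smear detector
   dropouts into their neighbours.

4. **Foot-strike detection** (`detect_foot_strikes()`). Each ankle's
   vertical position is differentiated (central difference; image y is
   negated so up is positive). A landing foot decelerates from its peak
   downward velocity to rest at contact, so the detector segments the
   downward-speed signal into step cycles at its prominent maxima and
   places the strike at the first sample after each cycle peak where the
   speed falls through 35% of that cycle's maximum. Two numerical guards
   are not part of the 35% rule itself but make it robust: (a) the
   bout-median downward speed is subtracted first, removing the slow drift
   that a walker approaching the camera imprints on every keypoint (zero
   for a drift-free signal, so constructed test signals are unaffected);
   (b) strikes and cycle peaks closer than 0.25 s are merged, suppressing
   double crossings — a plausible floor on human step time, configurable.
   The threshold is relative per cycle, which makes detection invariant to
   pixel scaling and to constant position offsets.

5. **Feature computation** (`extract_features()`). Seven variables per bout:

   - **Cadence**: total merged foot strikes divided by bout duration in
     minutes.
   - **Symmetry index (SI)** of step timing:
     $|T_L - T_R| \,/\, \left((T_L + T_R)/2\right)$, where $T_f$ is the
     step time attributed to foot $f$ (each step belongs to the foot whose
     strike ends it). The denominator uses attributed time, not wall-clock
     time, so unwalked lead-in does not dilute asymmetry; wall-clock is
     available via the `total_s` argument.
   - **CV of step time**: sample standard deviation over mean of the merged
     step durations (n−1 denominator throughout).
   - **Average step width**: per frame, the horizontal ankle separation
     divided by that frame's hip span, averaged over frames.
   - **CV of step width**: widths sampled once per step, at each strike
     frame, so the variability is per-step like the step-time CV; a
     per-frame width series is also exposed for diagnostics.
   - **Average and minimum eMOS**: margin-of-stability measures built on an
     inverted pendulum. The estimated centre of mass (eCOM) is the hip
     midpoint; the extrapolated centre of mass adds the velocity term,
     $\mathrm{eXCOM} = \mathrm{eCOM} + v / \sqrt{g / \ell}$, with the
     mediolateral velocity $v$ in hip-span units/s and $\ell$ the
     normalized leg length (hip-to-ankle distance sampled at strike
     frames, averaged per foot and then across feet). The construction is
     deliberately unitless: $g = 9.81$ enters against a normalized length,
     mirroring the relative nature of every other measure; both are
     configurable. Per frame, eMOS is the signed horizontal distance from
     the eXCOM to the stance ankle — positive when the ankle is lateral of
     the eXCOM (further from the body midline, taken as the eCOM). The
     stance foot is the foot of the most recent strike, the simplest rule
     consistent with single support; frames before the first strike are
     skipped. `avg_emos` averages all stance-assigned frames; `min_emos`
     averages each step's minimum over the steps (intervals between
     consecutive merged strikes; the partial tail after the last strike is
     not a step).

Every pixel quantity is normalized per frame by default (`span_policy =
"per_frame"`), which is what makes the features invariant to the
perspective growth of an approaching walker; a bout-median policy is
available for recordings where the span collapses in single frames. Frames
whose hip span is at or below a 1 px floor are dropped from whichever
statistic is being computed.

Bouts are discarded when manually flagged at collection time (handrail use,
turning around, occlusion — accepted as input flags, since they reflect
judgments the pipeline cannot make) or when fewer than 3 foot strikes are
detected; the boundary is inclusive, 3 strikes retain the bout. Features
whose preconditions fail (e.g. SI when one foot has no attributed step) are
reported as missing, never as zero.

## Keypoint verification

`pckh()` scores detector output against manual annotations with the
head-normalized PCK metric: a prediction is correct when its Euclidean
distance to the annotation is at most $\alpha$ times that image's head
segment (annotated `head_top`–`neck` distance), with ties counting as
correct and $\alpha = 0.5$ by default. `confidence_sweep()` repeats the
evaluation after discarding predictions below each confidence cutoff
(0.2, 0.4, 0.6, 0.8 by default), reporting the accuracy/coverage trade-off
that motivates the 0.4 gating default.

## Baselines and cohort models

Per-participant baselines average each feature over retained bouts recorded
within 14 days of enrollment (inclusive). `run_stats()` then fits:

- univariate OLS of each feature to the POMA-gait and POMA-balance
  sub-scores (two-sided t test on the slope);
- univariate Poisson regression of fall counts on each feature with
  `log(exposure_days)` as an offset, so coefficients describe fall rates
  (two-sided Wald z test);
- a multivariate Poisson model built by rule: keep features univariately
  significant at 0.05; among any pair correlating above $|r| = 0.8$, keep
  the one with the higher univariate pseudo-R². The 0.8 cutoff is our
  choice of "highly correlated"; it is configurable, and the pruning is
  greedy from the strongest association downward.

For Poisson models we report the deviance pseudo-R²,
$1 - D_{\text{res}}/D_{\text{null}}$ (null = intercept + offset), with the
predictor-count adjustment $1 - (1 - R^2)(n-1)/(n-k-1)$. An adjusted value
is by construction no larger than the unadjusted one; we make the formula
explicit precisely because "adjusted R²" is reported without definition
often enough to be ambiguous. A constant outcome in the linear models is
reported as $R^2 = 0$ (there is no variance to explain). Zero-variance
features raise a classed degenerate-design error that the pipeline converts
to a marked table row rather than a crash.

## What the synthetic generator does and does not emulate

`simulate_bout()` produces the geometry the pipeline is built for: a
13-keypoint skeleton approaching a ceiling-mounted hallway camera at 30 fps.
Its kinematic choices:

- **Perspective** is isotropic linear scale growth (default 1.5× over a
  12 s bout) — adequate for exercising the hip-span normalization, with no
  full pinhole projection.
- **Sway**: hips oscillate mediolaterally once per stride.
- **Swing arcs**: the stance ankle is quasi-static while the swing ankle
  traces a half-sine vertical arc into each programmed strike (default
  height 0.5 hip spans, swing occupying 40% of the stride). The half-sine
  is a modelling convenience, not a claim about real gait: it yields a
  clean descending velocity limb for the 35% rule while giving a non-zero
  contact velocity like a real heel strike.
- **Timing**: strikes alternate feet with intervals set by the programmed
  cadence and a stance-time split (0.55 programs an SI of 0.2).
- **Detector error**: Gaussian pixel noise (default 1 px), plus a dropout
  fraction (default 5%) of keypoints that are displaced and assigned
  confidence below the gate — so imputation, not filtering, must absorb
  them. An optional half-scale "assistant" track exercises track selection.

Ground truth (contact times, stance intervals, per-step widths, the true
feature vector, the noise-free skeleton) is emitted alongside, and truth
features are computed from the emitted kinematics with the same defining
formulas — e.g. the true cadence of a finite bout is the realized strike
count over its duration, which can differ from the programmed rate by a
boundary step, and the realized stance split depends on which foot gets the
odd interval.

What passing recovery tests on this generator shows is that the event
detector, normalization and feature formulas are correct and robust to the
modelled noise; it does *not* show robustness to everything real videos
contain — pose-estimator identity switches between people, limb occlusion by
walkers, non-straight paths, or correlated (non-Gaussian) keypoint error.
Those failure modes are exactly why the manual exclusion flags and the PCKh
verification stage exist.

`simulate_cohort()` draws 31 participants' baseline features from a
multivariate normal whose defaults echo a small specialized-dementia-unit
study: exposures of roughly 44 ± 19 days, a strong (0.9) correlation
between the two eMOS variants, modest (0.2) correlation elsewhere, and fall
counts Poisson in the exposure with a log-linear rate in centred features
(base rate 0.032/day at the mean profile, about 1.4 falls over 44 days).
The default nonzero coefficients (cadence +0.03 per step/min, step width
−1, average eMOS −10 per hip-span unit) were fixed once by a power
consideration: at n = 31 and these exposures, the eMOS effect must be
strongly detectable for the collinearity-pruning rule to face its intended
situation — two correlated, individually significant variants of which
exactly one should survive. Under these defaults the heavy tail of the rate
distribution occasionally produces fall counts above the single digits;
that is the price of a clearly identifiable effect at this sample size.
POMA sub-scores are linear in designated features plus noise, rounded and
clipped to their valid ranges (0–12 gait, 0–16 balance).

## Numerical conventions, edge cases, problem sizes

- Image coordinates: y grows downward; all vertical computations negate it
  internally. Frames are 0-based; `time_s = frame / fps`.
- Missing keypoints are carried explicitly (coordinates `NA`, confidence
  0), never silently dropped; a required keypoint with fewer than two
  accepted samples rejects the bout with a classed error that the pipeline
  logs as a discard reason.
- The pose JSON writer emits 17 significant digits, so bouts round-trip
  bit-exactly.
- eMOS sign: positive-lateral; signed values are averaged, so a crossing
  eXCOM genuinely reduces the average. The sign at exact coincidence of
  ankle and midline is +1.
- Verification sizes: recovery properties use 100 seeded bouts spanning
  cadence 60–130 steps/min, width ratios 0.2–1.0, noise up to 2 px and
  dropout up to 15%; statistical calibration uses 2000 null cohorts (test
  size), 500 effect cohorts (estimator bias) and 200 cohorts for the
  selection rule. These sizes give Monte-Carlo error comfortably below the
  tolerances being checked while keeping the default test run quick.

## Limitations

- No absolute spatial gait variables: a 2D projection has no depth, and the
  package deliberately offers no step length or velocity.
- The stance rule (most recent strike) misassigns frames inside true double
  support; the generator's truth-based checks exclude such frames and
  accept ≥90% frame agreement.
- The 35% crossing rule is under-determined in the literature it comes
  from; our reading (descending limb after the per-cycle peak of downward
  speed) is one defensible choice, made testable by the brute-force oracle
  that re-evaluates the definition sample by sample.
- Whether "time spent on each foot" in the symmetry index means attributed
  step time or stance time is ambiguous; we use attributed step time and
  expose the denominator. Likewise `min_emos` averages per-step minima
  rather than taking a single bout minimum — the reading that keeps the
  statistic stable against one bad frame.
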