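# gaitvision

Markerless gait analysis and fall-risk modelling from 2D pose keypoints.

Older adults with dementia fall frequently, and conventional clinic-based
gait assessment is hard to deliver in that population. An alternative is
ambient monitoring: a fixed hallway camera records short walking bouts, a
2D human-pose estimator tracks body keypoints frame by frame, and gait
variables are computed from the keypoint time series. gaitvision implements
that analysis end to end for researchers working with pose-estimator output
(OpenPose-style per-frame JSON):

- **Ingestion & QC** — read/write the pose JSON dialect, select the
  participant's track among multiple detected people (largest median hip
  span by default), flag bouts with too few steps or manual exclusions.
- **Preprocessing** — confidence gating (< 0.4 discarded) with linear
  imputation, zero-phase 2nd-order Butterworth low-pass filtering (4 Hz),
  and normalization of every pixel distance by the mediolateral hip span,
  which removes camera-distance scale.
- **Gait events & features** — foot strikes from ankle vertical velocity
  (35% of the per-cycle peak downward speed, crossed on the landing limb),
  then seven per-bout variables: cadence, step-time symmetry index
  `|T_L − T_R| / ((T_L + T_R)/2)`, CV of step time, average and CV of step
  width (hip-span units), and average/minimum estimated margin of
  stability, `eMOS = (stance ankle − eXCOM)` with
  `eXCOM = eCOM + v/√(g/ℓ)` built from the hip midpoint.
- **Verification** — PCKh@0.5 keypoint accuracy against manual
  annotations, with confidence-cutoff sweeps.
- **Cohort statistics** — baseline averaging over a 14-day enrollment
  window; univariate linear models of each feature to POMA-gait and
  POMA-balance; univariate and multivariate Poisson models of prospective
  fall counts with a log-exposure offset, using deviance pseudo-R² and a
  significance-then-collinearity selection rule.
- **Synthetic data** — a seeded generator of walking bouts (perspective
  scale growth, sway, half-sine swing arcs, pixel noise, confidence
  dropouts, optional second person) and participant cohorts with known
  ground truth, so the whole pipeline is verifiable without clinical video.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()` on
fitted models, `autoplot()` on bouts and PCK reports.

## Worked example

Simulate a bout walking toward the camera at 105 steps/min with a step
width of 0.45 hip spans, and extract its features:

```r
library(gaitvision)

sim <- simulate_bout(gait_sim_params(seed = 42, cadence = 105,
                                     step_width_ratio = 0.45))
fv  <- extract_features(sim$bout)
round(fv[, c(gait_feature_names(), "n_steps", "duration_s")], 4)
#>   cadence si_step_time cv_step_time avg_step_width cv_step_width avg_emos
#> 1     100       0.1227       0.0218         0.4518        0.0402   0.1795
#>   min_emos n_steps duration_s
#> 1  -0.1149      20         12
```

The detector found all 20 true strikes (cadence 100 = 20 strikes / 0.2 min;
the realized rate of a finite bout differs from the programmed 105 by a
boundary step, and `sim$truth$features` carries the realized truth). Width
0.4518 recovers the programmed 0.45 under noise; the small symmetry index
reflects the odd/even composition of step intervals in a finite bout; the
negative minimum eMOS says the extrapolated centre of mass overtakes the
stance ankle laterally at some point in most steps.

Cohort-level association models on a simulated 31-participant cohort:

```r
cohort <- simulate_cohort(cohort_sim_params(seed = 7))
st <- run_stats(
  cohort$records[, c("participant_id", gait_feature_names())],
  cohort$records[, c("participant_id", "poma_gait", "poma_balance",
                     "n_falls", "exposure_days")]
)
st$falls_multivariate
#> # A tibble: 4 × 8
#>   term           estimate std.error statistic  p.value    r2 adjusted_r2     n
#>   <chr>             <dbl>     <dbl>     <dbl>    <dbl> <dbl>       <dbl> <int>
#> 1 (Intercept)     -1.44     1.13        -1.27 0.203    0.442       0.380    31
#> 2 cadence          0.0226   0.00849      2.66 0.00776  0.442       0.380    31
#> 3 avg_step_width  -4.05     1.29        -3.15 0.00164  0.442       0.380    31
#> 4 avg_emos        -7.14     2.13        -3.35 0.000811 0.442       0.380    31
```

The selection rule kept the univariately significant features and, of the
two highly correlated eMOS variants, only the stronger one (`avg_emos`);
higher cadence is associated with a higher fall rate, wider steps and a
larger margin of stability with a lower one. The deviance pseudo-R² of the
model is 0.442.

See `vignette("gait-from-pose")` for the model, parameter and design
details.

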