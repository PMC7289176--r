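#' Parameters for simulating a walking bout
#'
#' The simulator emulates the capture geometry the pipeline is built for: a
#' walker approaching a ceiling-mounted camera at the end of a hallway, so
#' the whole skeleton grows by a linear perspective scale over the bout.
#' Hips oscillate mediolaterally (sway) at the stride frequency; the stance
#' ankle is quasi-static while the swing ankle traces a half-sine vertical
#' arc into each programmed foot strike; ankle separation follows a
#' configurable step-width-to-hip-span ratio with optional per-step jitter;
#' Gaussian pixel noise and low-confidence dropouts mimic detector error.
#'
#' @param fps Frames per second (default 30).
#' @param duration_s Bout length in seconds (default 12).
#' @param cadence Programmed cadence in steps/min (default 100).
#' @param step_width_ratio Ankle separation in hip-span units (default 0.5).
#' @param stance_time_split Share of attributed step time on the left foot
#'   (0.5 = symmetric; 0.55 yields a symmetry index of 0.2).
#' @param hip_span_start_px Hip span at the first frame (default 40 px).
#' @param perspective_scale_end Size multiplier at the end of the bout
#'   (>= 1; default 1.5).
#' @param sway_amplitude Mediolateral hip sway amplitude in hip-span units
#'   (default 0.1).
#' @param leg_length_ratio Normalized hip-to-ankle length (default 3).
#' @param step_height_ratio Swing-arc height in hip-span units (default
#'   0.5).
#' @param swing_fraction Fraction of each stride spent in swing (default
#'   0.4).
#' @param width_jitter_cv Per-step multiplicative step-width jitter CV
#'   (default 0).
#' @param pixel_noise_sd Gaussian keypoint noise in px (default 1).
#' @param dropout_rate Fraction of keypoint samples assigned low confidence
#'   and displaced (default 0.05).
#' @param dropout_confidence Confidence range for dropped-out samples
#'   (default `c(0, 0.3)`, below the 0.4 gate).
#' @param good_confidence Confidence range for accepted samples (default
#'   `c(0.7, 1)`).
#' @param assistant Add a second half-scale "assistant" track (default
#'   `FALSE`).
#' @param seed RNG seed; the bout is deterministic given the parameter set.
#' @return A `gait_sim_params` list.
#' @export
gait_sim_params <- function(fps = 30, duration_s = 12, cadence = 100,
                            step_width_ratio = 0.5, stance_time_split = 0.5,
                            hip_span_start_px = 40,
                            perspective_scale_end = 1.5,
                            sway_amplitude = 0.1, leg_length_ratio = 3,
                            step_height_ratio = 0.5, swing_fraction = 0.4,
                            width_jitter_cv = 0, pixel_noise_sd = 1,
                            dropout_rate = 0.05,
                            dropout_confidence = c(0, 0.3),
                            good_confidence = c(0.7, 1),
                            assistant = FALSE, seed = 1) {
  p <- as.list(environment())
  stopifnot(
    p$fps > 0, p$duration_s > 0, p$cadence > 0,
    p$step_width_ratio > 0, p$step_width_ratio <= 1.5,
    p$stance_time_split > 0, p$stance_time_split < 1,
    p$perspective_scale_end >= 1, p$leg_length_ratio > 0,
    p$swing_fraction > 0, p$swing_fraction < 1,
    p$dropout_rate >= 0, p$dropout_rate < 1
  )
  structure(p, class = "gait_sim_params")
}

# skeleton proportions relative to the hip span (purely cosmetic keypoints;
# the gait math only uses hips, ankles and the head segment)
SKEL <- list(
  head_top = c(0, -2.6), neck = c(0, -2.0), thorax = c(0, -1.5),
  left_shoulder = c(-0.6, -2.0), right_shoulder = c(0.6, -2.0),
  left_elbow = c(-0.7, -0.8), right_elbow = c(0.7, -0.8)
)

strike_schedule <- function(p) {
  step_t <- 60 / p$cadence
  d_left <- 2 * step_t * p$stance_time_split      # interval ending in a left strike
  d_right <- 2 * step_t * (1 - p$stance_time_split)
  times <- numeric()
  feet <- character()
  t <- 0.5
  foot <- "left"
  while (t <= p$duration_s - 0.2) {
    times <- c(times, t)
    feet <- c(feet, foot)
    t <- t + if (foot == "left") d_right else d_left
    foot <- if (foot == "left") "right" else "left"
  }
  tibble(foot = feet, time_s = times)
}

clean_skeleton <- function(p, strikes, widths) {
  n <- round(p$duration_s * p$fps)
  frame <- 0:(n - 1L)
  t <- frame / p$fps
  scale_t <- 1 + (p$perspective_scale_end - 1) * t / p$duration_s
  span <- p$hip_span_start_px * scale_t
  stride_f <- p$cadence / 120 # sway once per stride (two steps)
  center_x <- 960 + p$sway_amplitude * span * sin(2 * pi * stride_f * t)
  hip_y <- 500 + 60 * (scale_t - 1)

  # step width ratio over time: linear between the per-strike values
  w_t <- if (nrow(strikes) >= 2L) {
    stats::approx(strikes$time_s, widths, xout = t, rule = 2)$y
  } else {
    rep(p$step_width_ratio, n)
  }

  # vertical drop chosen so the normalized hip-ankle length is
  # leg_length_ratio at the nominal width
  v_drop <- sqrt(p$leg_length_ratio^2 - ((1 - p$step_width_ratio) / 2)^2)

  swing_lift <- function(foot) {
    lift <- numeric(n)
    st <- strikes$time_s[strikes$foot == foot]
    if (!length(st)) return(lift)
    stride <- 120 / p$cadence
    for (i in seq_along(st)) {
      dur <- if (i == 1L) stride else st[i] - st[i - 1L]
      sw <- p$swing_fraction * dur
      in_swing <- t >= (st[i] - sw) & t < st[i]
      u <- (t[in_swing] - (st[i] - sw)) / sw
      lift[in_swing] <- sin(pi * u)
    }
    lift
  }
  lift_l <- swing_lift("left")
  lift_r <- swing_lift("right")

  base_y <- hip_y + v_drop * span
  arc <- p$step_height_ratio * span
  kp <- list(
    left_hip = cbind(center_x - span / 2, hip_y),
    right_hip = cbind(center_x + span / 2, hip_y),
    left_ankle = cbind(center_x - w_t * span / 2, base_y - arc * lift_l),
    right_ankle = cbind(center_x + w_t * span / 2, base_y - arc * lift_r)
  )
  kp$left_knee <- (kp$left_hip + kp$left_ankle) / 2
  kp$right_knee <- (kp$right_hip + kp$right_ankle) / 2
  for (nm in names(SKEL)) {
    kp[[nm]] <- cbind(center_x + SKEL[[nm]][1] * span,
                      hip_y + SKEL[[nm]][2] * span)
  }
  df <- purrr::imap(kp[default_keypoints()], function(m, nm) {
    tibble(frame = frame, time_s = t, keypoint = nm, x = m[, 1], y = m[, 2])
  }) |> bind_rows() |> arrange(.data$frame, .data$keypoint)
  list(df = df, span = span, center_x = center_x, v_drop = v_drop, w_t = w_t)
}

add_detector_noise <- function(df, p) {
  nr <- nrow(df)
  df$x <- df$x + rnorm(nr, 0, p$pixel_noise_sd)
  df$y <- df$y + rnorm(nr, 0, p$pixel_noise_sd)
  df$confidence <- runif(nr, p$good_confidence[1], p$good_confidence[2])
  drop <- runif(nr) < p$dropout_rate
  if (any(drop)) {
    # dropped-out detections are unreliable: displaced and low-confidence
    df$x[drop] <- df$x[drop] + rnorm(sum(drop), 0, 15)
    df$y[drop] <- df$y[drop] + rnorm(sum(drop), 0, 15)
    df$confidence[drop] <- runif(sum(drop), p$dropout_confidence[1],
                                 p$dropout_confidence[2])
  }
  df$dropout <- drop
  df
}

true_emos <- function(skel, strikes, p, g = 9.81) {
  fps <- p$fps
  span <- skel$span
  ecom_x <- skel$center_x
  t <- sort(unique(skel$df$time_s))
  v_norm <- finite_diff(ecom_x, fps) / span
  ll <- sqrt(skel$v_drop^2 + ((1 - skel$w_t) / 2)^2)
  leg_length <- mean(ll[round(strikes$time_s * fps) + 1L])
  offset <- v_norm / sqrt(g / leg_length)
  stance <- stance_foot(t, strikes)
  ankle_x <- ifelse(stance == "left",
                    ecom_x - skel$w_t * span / 2,
                    ecom_x + skel$w_t * span / 2)
  s <- ifelse(stance == "left", -1, 1)
  m <- s * ((ankle_x - ecom_x) / span - offset)
  use <- t >= min(strikes$time_s)
  steps <- step_times(strikes)
  idx <- findInterval(t[use], steps$start_s)
  in_step <- idx >= 1L & t[use] < max(steps$end_s)
  mins <- tapply(m[use][in_step], idx[in_step], min)
  list(avg_emos = mean(m[use]), min_emos = mean(mins),
       leg_length = leg_length)
}

#' Simulate a walking bout with known ground truth
#'
#' @param params A [gait_sim_params()] list.
#' @return A list with:
#' \describe{
#'   \item{pose}{A multi-track pose-frame table, as [read_pose_json()] would
#'     return (two tracks when `assistant = TRUE`).}
#'   \item{bout}{The participant's `walking_bout` (explicit-id selection);
#'     pre-flagged `too_few_steps` when the parameters program fewer than 3
#'     strikes.}
#'   \item{truth}{Ground truth: `strikes` (true contact times per foot),
#'     `stance` (function mapping times to the true stance foot),
#'     `step_widths`, `clean` (noise-free participant keypoints),
#'     `participant_track`, and `features`, the true seven-feature vector
#'     computed from the generating kinematics.}
#' }
#' @export
simulate_bout <- function(params = gait_sim_params()) {
  p <- params
  set.seed(p$seed)
  strikes <- strike_schedule(p)
  jitter <- if (p$width_jitter_cv > 0) {
    pmax(0.1, 1 + rnorm(nrow(strikes), 0, p$width_jitter_cv))
  } else {
    rep(1, nrow(strikes))
  }
  widths <- p$step_width_ratio * jitter
  skel <- clean_skeleton(p, strikes, widths)

  part <- add_detector_noise(skel$df, p)
  part$track <- "participant"
  tracks <- part
  if (isTRUE(p$assistant)) {
    q <- p
    q$hip_span_start_px <- p$hip_span_start_px / 2
    helper <- clean_skeleton(q, strikes, widths / 2)
    helper$df$x <- helper$df$x / 2 + 250
    helper$df$y <- helper$df$y / 2 + 150
    asst <- add_detector_noise(helper$df, p)
    asst$track <- "assistant"
    tracks <- bind_rows(part, asst)
  }
  pose_df <- tracks[, c("frame", "time_s", "track", "keypoint", "x", "y",
                        "confidence")]
  pose <- new_pose_frames(
    arrange(pose_df, .data$frame, .data$track, .data$keypoint),
    fps = p$fps, schema = default_keypoints(),
    bout_id = paste0("sim-", p$seed),
    participant_id = "SIM01",
    recorded_at = "2020-01-01"
  )
  flags <- if (nrow(strikes) < 3L) "too_few_steps" else character()
  bout <- select_participant_track(pose, policy = "explicit_id",
                                   track_id = "participant", flags = flags)

  dur <- round(p$duration_s * p$fps) / p$fps
  steps <- step_times(strikes)
  pf <- per_foot_time(steps)
  mos <- if (nrow(strikes) >= 2L) true_emos(skel, strikes, p) else
    list(avg_emos = NA_real_, min_emos = NA_real_, leg_length = NA_real_)
  truth_features <- tibble(
    cadence = nrow(strikes) * 60 / dur,
    si_step_time = if (all(pf > 0)) abs(pf[["left"]] - pf[["right"]]) / (sum(pf) / 2)
      else NA_real_,
    cv_step_time = cv(steps$duration_s),
    avg_step_width = mean(skel$w_t),
    cv_step_width = cv(widths),
    avg_emos = mos$avg_emos,
    min_emos = mos$min_emos
  )
  truth <- list(
    strikes = strikes,
    stance = function(time_s) stance_foot(time_s, strikes),
    step_widths = widths,
    clean = skel$df,
    leg_length = mos$leg_length,
    participant_track = "participant",
    features = truth_features,
    dropout_mask = part$dropout
  )
  list(pose = pose, bout = bout, truth = truth)
}

#' Annotation fixture with controlled prediction error
#'
#' Builds a matched (predictions, annotations) pair for exercising the PCKh
#' evaluation: the annotations are the supplied (noise-free) keypoints; the
#' predictions add Gaussian jitter, with a chosen fraction displaced by
#' twice the head-segment length (guaranteed incorrect at PCKh@0.5), and
#' confidences anti-correlated with displacement.
#'
#' @param keypoints Tibble of true keypoints: `frame` (or `image_id`),
#'   `keypoint`, `x`, `y` — e.g. a few frames of `truth$clean` from
#'   [simulate_bout()].
#' @param jitter_sd_px Gaussian jitter SD in px (default 2).
#' @param inaccurate_fraction Fraction of points displaced far beyond the
#'   threshold (default 0).
#' @param seed RNG seed.
#' @return A list with `predictions` (incl. `confidence`) and `annotations`
#'   tibbles keyed by `image_id` and `keypoint`.
#' @export
make_annotation_fixture <- function(keypoints, jitter_sd_px = 2,
                                    inaccurate_fraction = 0, seed = 1) {
  set.seed(seed)
  ann <- as_tibble(keypoints)
  if (!"image_id" %in% names(ann)) {
    ann$image_id <- paste0("img", ann$frame)
  }
  ann <- ann[, c("image_id", "keypoint", "x", "y")]
  heads <- head_segment_lengths(ann)
  pred <- ann |>
    inner_join(heads, by = "image_id") |>
    mutate(
      x = .data$x + rnorm(n(), 0, jitter_sd_px),
      y = .data$y + rnorm(n(), 0, jitter_sd_px)
    )
  n_bad <- round(inaccurate_fraction * nrow(pred))
  bad <- sample(nrow(pred), n_bad)
  if (n_bad > 0) {
    theta <- runif(n_bad, 0, 2 * pi)
    pred$x[bad] <- pred$x[bad] + 2 * pred$head_length[bad] * cos(theta)
    pred$y[bad] <- pred$y[bad] + 2 * pred$head_length[bad] * sin(theta)
  }
  displacement <- sqrt((pred$x - ann$x)^2 + (pred$y - ann$y)^2)
  # anti-correlated with error, graded so displaced points spread across the
  # usual cutoff range rather than collapsing to zero confidence
  pred$confidence <- pmin(1, pmax(
    0, 1 - displacement / (2.5 * pred$head_length) +
      rnorm(nrow(pred), 0, 0.08)
  ))
  list(
    predictions = pred[, c("image_id", "keypoint", "x", "y", "confidence")],
    annotations = ann
  )
}

#' Parameters for simulating a participant cohort
#'
#' Defaults echo the scale of a small specialized-dementia-unit study:
#' 31 participants observed for roughly 44 +/- 19 days, fall counts mostly
#' between 0 and 8, POMA-gait scores around 8 of 12, and a strong positive
#' correlation between the two eMOS variants.
#'
#' @param n_participants Cohort size (default 31).
#' @param feature_means,feature_sds Named vectors over the seven features.
#' @param corr Inter-feature correlation matrix (default: 0.2 everywhere
#'   off-diagonal, 0.9 between `avg_emos` and `min_emos`).
#' @param beta Named Poisson log-rate coefficients per feature (features are
#'   centred at their means inside the model, so `base_rate_per_day` is the
#'   fall rate at the mean profile).
#' @param base_rate_per_day Fall rate at the mean feature profile (default
#'   0.032/day, i.e. about 1.4 falls over 44 days).
#' @param exposure_mean,exposure_sd,exposure_min Observation-time
#'   distribution in days.
#' @param poma_gait_coef,poma_balance_coef Named linear coefficients from
#'   (centred) features to the POMA sub-scores.
#' @param poma_noise_sd Score noise SD before rounding/clipping.
#' @param seed RNG seed.
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_participants = 31,
                              feature_means = c(
                                cadence = 95, si_step_time = 0.15,
                                cv_step_time = 0.10, avg_step_width = 0.6,
                                cv_step_width = 0.15, avg_emos = 0.25,
                                min_emos = 0.15
                              ),
                              feature_sds = c(
                                cadence = 15, si_step_time = 0.08,
                                cv_step_time = 0.04, avg_step_width = 0.15,
                                cv_step_width = 0.05, avg_emos = 0.08,
                                min_emos = 0.08
                              ),
                              corr = NULL,
                              beta = c(
                                cadence = 0.03, si_step_time = 0,
                                cv_step_time = 0, avg_step_width = -1,
                                cv_step_width = 0, avg_emos = -10,
                                min_emos = 0
                              ),
                              base_rate_per_day = 0.032,
                              exposure_mean = 44, exposure_sd = 19,
                              exposure_min = 7,
                              poma_gait_coef = c(cadence = -0.10),
                              poma_balance_coef = c(cadence = -0.12,
                                                    avg_step_width = 4),
                              poma_noise_sd = 1.8,
                              seed = 1) {
  feats <- gait_feature_names()
  if (is.null(corr)) {
    corr <- matrix(0.2, 7, 7, dimnames = list(feats, feats))
    diag(corr) <- 1
    corr["avg_emos", "min_emos"] <- corr["min_emos", "avg_emos"] <- 0.9
  }
  stopifnot(
    identical(sort(names(feature_means)), sort(feats)),
    identical(sort(names(feature_sds)), sort(feats)),
    all(eigen(corr, symmetric = TRUE, only.values = TRUE)$values > -1e-8),
    exposure_min > 0
  )
  structure(as.list(environment())[
    c("n_participants", "feature_means", "feature_sds", "corr", "beta",
      "base_rate_per_day", "exposure_mean", "exposure_sd", "exposure_min",
      "poma_gait_coef", "poma_balance_coef", "poma_noise_sd", "seed")
  ], class = "cohort_sim_params")
}

clip_score <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Simulate a participant cohort with known association structure
#'
#' Baseline features are drawn from a multivariate normal with the stated
#' means, SDs and correlation; fall counts are Poisson with rate
#' `exposure_days * base_rate * exp(beta . (x - mu))`; POMA sub-scores are
#' linear in designated (centred) features plus noise, rounded and clipped
#' to their valid ranges (0-12 gait, 0-16 balance).
#'
#' @param params A [cohort_sim_params()] list.
#' @return A list with `records` (tibble: `participant_id`, the seven
#'   features, `poma_gait`, `poma_balance`, `n_falls`, `exposure_days`) and
#'   `truth` (the generating parameters).
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  p <- params
  set.seed(p$seed)
  feats <- gait_feature_names()
  mu <- p$feature_means[feats]
  sds <- p$feature_sds[feats]
  Sigma <- diag(sds) %*% p$corr[feats, feats] %*% diag(sds)
  X <- MASS::mvrnorm(p$n_participants, mu, Sigma)
  colnames(X) <- feats
  Xc <- sweep(X, 2, mu)

  exposure <- pmax(p$exposure_min,
                   rnorm(p$n_participants, p$exposure_mean, p$exposure_sd))
  beta <- setNames(rep(0, 7), feats)
  beta[names(p$beta)] <- p$beta
  eta <- log(p$base_rate_per_day) + drop(Xc %*% beta)
  n_falls <- rpois(p$n_participants, exposure * exp(eta))

  lin_score <- function(coefs, base) {
    v <- setNames(rep(0, 7), feats)
    v[names(coefs)] <- coefs
    base + drop(Xc %*% v) + rnorm(p$n_participants, 0, p$poma_noise_sd)
  }
  records <- tibble(
    participant_id = sprintf("P%02d", seq_len(p$n_participants)),
    as_tibble(X),
    poma_gait = clip_score(lin_score(p$poma_gait_coef, 8.2), 0, 12),
    poma_balance = clip_score(lin_score(p$poma_balance_coef, 8.8), 0, 16),
    n_falls = n_falls,
    exposure_days = exposure
  )
  list(records = records,
       truth = list(beta = beta, base_rate_per_day = p$base_rate_per_day,
                    mu = mu, Sigma = Sigma))
}
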