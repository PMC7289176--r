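# Shared fixtures and independent oracles, built in code at test time.

# Minimal hand-built walking bout: supply per-keypoint coordinate functions
# of the frame index (0-based); everything else gets sensible defaults.
toy_bout <- function(n_frames, fps = 30, coords = list(), conf = 1,
                     flags = character(), bout_id = "toy") {
  schema <- default_keypoints()
  frames <- 0:(n_frames - 1)
  default_xy <- list(
    left_hip = function(f) cbind(100, 200),
    right_hip = function(f) cbind(140, 200),
    left_ankle = function(f) cbind(105, 320),
    right_ankle = function(f) cbind(135, 320),
    head_top = function(f) cbind(120, 80),
    neck = function(f) cbind(120, 110)
  )
  coords <- utils::modifyList(default_xy, coords)
  rows <- lapply(schema, function(kp) {
    fn <- coords[[kp]]
    xy <- if (is.null(fn)) cbind(rep(120, length(frames)), rep(150, length(frames)))
      else {
        m <- fn(frames)
        if (nrow(m) == 1L) m <- m[rep(1, length(frames)), , drop = FALSE]
        m
      }
    tibble::tibble(
      frame = frames, time_s = frames / fps, track = "t1", keypoint = kp,
      x = xy[, 1], y = xy[, 2],
      confidence = if (length(conf) == 1L) rep(conf, length(frames)) else conf
    )
  })
  df <- dplyr::arrange(dplyr::bind_rows(rows), frame, keypoint)
  pose <- gaitvision:::new_pose_frames(
    df, fps = fps, schema = schema, bout_id = bout_id,
    participant_id = "T01", recorded_at = "2020-01-01"
  )
  select_participant_track(pose, policy = "explicit_id", track_id = "t1",
                           flags = flags)
}

# Squared magnitude response of the designed Butterworth filter at f Hz --
# the analytic oracle for zero-phase (forward-backward) attenuation.
butter_gain2 <- function(fs, cutoff_hz, order, f) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

# Exact amplitude of a sinusoid at frequency f in a series (least squares on
# sin/cos basis over the central portion, away from edges).
sin_amplitude <- function(x, fs, f, trim = 0.2) {
  n <- length(x)
  idx <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  t <- (idx - 1) / fs
  fit <- stats::lm(x[idx] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# Brute-force foot-strike oracle: naive per-sample evaluation of the
# 35%-crossing rule, independent of the vectorised implementation.
brute_force_strikes <- function(velocity, fs, threshold_frac = 0.35,
                                min_step_interval_s = 0.25,
                                min_peak_frac = 0.3) {
  d <- pmax(-velocity, 0)
  n <- length(d)
  if (max(d) <= 0) return(integer())
  # every strict local maximum tall enough
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (d[i] >= d[i - 1] && d[i] > d[i + 1] && d[i] >= min_peak_frac * max(d)) {
      peaks <- c(peaks, i)
    }
  }
  if (is.null(peaks)) return(integer())
  min_gap <- max(1, round(min_step_interval_s * fs))
  kept <- c()
  for (p in peaks[order(d[peaks], decreasing = TRUE)]) {
    if (all(abs(kept - p) >= min_gap) || length(kept) == 0) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  strikes <- c()
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    bound <- if (k < length(peaks)) peaks[k + 1] - 1 else n
    found <- NA
    for (j in (p + 1):bound) {
      if (j > n) break
      if (d[j] < threshold_frac * d[p]) { found <- j; break }
    }
    if (!is.na(found)) strikes <- c(strikes, found)
  }
  if (length(strikes) > 1) {
    out <- strikes[1]
    for (s in strikes[-1]) if (s - out[length(out)] >= min_gap) out <- c(out, s)
    strikes <- out
  }
  as.integer(strikes - 1)
}

# Random pulse-train velocity signal for oracle-equivalence checks: a series
# of downward (negative up-velocity) triangular pulses of varying height,
# width and spacing.
random_pulse_velocity <- function(seed, fs = 30, n_pulses = 6) {
  set.seed(seed)
  v <- numeric(0)
  for (i in seq_len(n_pulses)) {
    gap <- rep(0, sample(10:25, 1))
    h <- runif(1, 40, 140)
    half <- sample(3:7, 1)
    pulse <- -h * c(seq(0, 1, length.out = half + 1)[-1],
                    seq(1, 0, length.out = half + 1)[-1])
    v <- c(v, gap, pulse)
  }
  c(v, rep(0, 12))
}
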