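#' Vertical velocity of a keypoint, up-positive
#'
#' Image coordinates have `y` increasing downward; gait conventions have "up"
#' positive, so the derivative is negated. Differentiation is by central
#' finite difference, one-sided at the series ends, scaled to px/s.
#'
#' @param y Pixel `y` series (image coordinates).
#' @param fs Sampling rate in Hz.
#' @return Velocity series of the same length, in px/s with up positive.
#' @export
vertical_velocity <- function(y, fs) {
  -finite_diff(y, fs)
}

finite_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1L]
  d * fs
}

local_maxima <- function(d) {
  n <- length(d)
  if (n < 3L) return(integer())
  which(d[2:(n - 1L)] >= d[1:(n - 2L)] & d[2:(n - 1L)] > d[3:n]) + 1L
}

#' Detect foot strikes from an ankle vertical-velocity series
#'
#' A landing foot decelerates from its peak downward velocity to rest at
#' ground contact. The signal is segmented into candidate step cycles by
#' prominent maxima of the downward speed; within each cycle the strike is
#' the first sample after the cycle's peak where the downward speed falls
#' through `threshold_frac` (default 35%) of that cycle's maximum. The
#' threshold is relative per cycle, so detection is invariant to pixel
#' scaling and to constant offsets of the position series. Before
#' thresholding, the bout-median downward speed is subtracted: a walker
#' approaching the camera sinks slowly in the image even during stance, and
#' the median captures exactly that drift (it is zero for a drift-free
#' signal).
#'
#' @param velocity Up-positive vertical-velocity series of one ankle
#'   (see [vertical_velocity()]).
#' @param fs Sampling rate in Hz.
#' @param threshold_frac Fraction of the per-cycle peak downward speed at
#'   which the strike is placed (default 0.35).
#' @param min_step_interval_s Minimum separation between two retained strikes
#'   of the same foot (default 0.25 s); guards against double crossings.
#' @param min_peak_frac Cycle peaks below this fraction of the global maximum
#'   downward speed are not treated as steps (default 0.3).
#' @return Integer vector of 0-based frame indices of the strikes (possibly
#'   empty, e.g. for a flat signal).
#' @export
detect_foot_strikes <- function(velocity, fs, threshold_frac = 0.35,
                                min_step_interval_s = 0.25,
                                min_peak_frac = 0.3) {
  d <- -velocity # downward speed
  # remove the slow baseline drift a walker approaching the camera imprints
  # on every keypoint (the stance ankle sinks in the image as scale grows);
  # for a drift-free signal the median is 0 and this is a no-op
  d <- pmax(d - median(d), 0)
  dmax <- max(d)
  if (!is.finite(dmax) || dmax <= 0) return(integer())

  peaks <- local_maxima(d)
  peaks <- peaks[d[peaks] >= min_peak_frac * dmax]
  if (!length(peaks)) return(integer())

  # keep the tallest peak in any conflict closer than the minimum interval
  min_gap <- max(1L, round(min_step_interval_s * fs))
  ord <- peaks[order(d[peaks], decreasing = TRUE)]
  kept <- integer()
  for (p in ord) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  peaks <- sort(kept)

  n <- length(d)
  strikes <- integer()
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    bound <- if (i < length(peaks)) peaks[i + 1L] - 1L else n
    thr <- threshold_frac * d[p]
    j <- p + 1L
    hit <- NA_integer_
    while (j <= bound) {
      if (d[j] < thr) {
        hit <- j
        break
      }
      j <- j + 1L
    }
    if (!is.na(hit)) strikes <- c(strikes, hit)
  }
  if (length(strikes) > 1L) {
    keep <- c(TRUE, diff(strikes) >= min_gap)
    strikes <- strikes[keep]
  }
  strikes - 1L # 0-based frames
}

#' Foot strikes for both ankles of a bout
#'
#' Runs [vertical_velocity()] and [detect_foot_strikes()] on each ankle of a
#' filtered trajectory and merges the two feet into one ordered event table.
#'
#' @param traj A filtered `pose_trajectory`.
#' @param config Pipeline parameters (see [pipeline_config()]); the relevant
#'   entries are `threshold_frac`, `min_step_interval_s`, `min_peak_frac`.
#' @return A tibble with columns `foot` (`"left"`/`"right"`), `frame`
#'   (0-based) and `time_s`, ordered by time.
#' @export
foot_strikes <- function(traj, config = pipeline_config()) {
  fs <- bout_fps(traj)
  one_foot <- function(foot) {
    kp <- paste0(foot, "_ankle")
    y <- traj$y[traj$keypoint == kp][order(traj$frame[traj$keypoint == kp])]
    v <- vertical_velocity(y, fs)
    idx <- detect_foot_strikes(
      v, fs,
      threshold_frac = config$threshold_frac,
      min_step_interval_s = config$min_step_interval_s,
      min_peak_frac = config$min_peak_frac
    )
    tibble(foot = foot, frame = idx, time_s = idx / fs)
  }
  ev <- bind_rows(one_foot("left"), one_foot("right"))
  arrange(ev, .data$time_s, .data$foot)
}

#' Step durations and per-foot attributed time
#'
#' Steps are counted on the merged two-foot strike sequence: each step is the
#' interval between consecutive strikes (of either foot) and is attributed to
#' the foot whose strike terminates it.
#'
#' @param events Strike table from [foot_strikes()] (columns `foot`,
#'   `time_s`).
#' @return A tibble with one row per step: `foot` (terminating foot),
#'   `start_s`, `end_s`, `duration_s`. Empty when fewer than 2 strikes.
#' @export
step_times <- function(events) {
  ev <- arrange(events, .data$time_s)
  if (nrow(ev) < 2L) {
    return(tibble(foot = character(), start_s = numeric(),
                  end_s = numeric(), duration_s = numeric()))
  }
  tibble(
    foot = ev$foot[-1L],
    start_s = ev$time_s[-nrow(ev)],
    end_s = ev$time_s[-1L],
    duration_s = diff(ev$time_s)
  )
}

#' @rdname step_times
#' @return `per_foot_time()`: named numeric vector of total step time
#'   attributed to each foot (seconds; 0 for a foot with no attributed
#'   steps).
#' @param steps A step table from [step_times()].
#' @export
per_foot_time <- function(steps) {
  out <- c(left = 0, right = 0)
  if (nrow(steps)) {
    agg <- tapply(steps$duration_s, steps$foot, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Stance-foot assignment per frame
#'
#' The stance foot at a time point is the foot with the most recent strike at
#' or before that time; times before the first strike are assigned the foot
#' of the first strike.
#'
#' @param time_s Numeric vector of query times (seconds).
#' @param events Strike table from [foot_strikes()].
#' @return Character vector (`"left"`/`"right"`) parallel to `time_s`.
#' @export
stance_foot <- function(time_s, events) {
  ev <- arrange(events, .data$time_s)
  if (nrow(ev) == 0L) {
    abort("No foot strikes in bout; stance is undefined.",
          class = "gaitvision_bout_rejected")
  }
  idx <- findInterval(time_s, ev$time_s)
  idx[idx == 0L] <- 1L
  ev$foot[idx]
}
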