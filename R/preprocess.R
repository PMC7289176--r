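#' Confidence gating and linear imputation
#'
#' Keypoints detected with confidence below `conf_threshold` (strictly below:
#' a score exactly at the threshold is kept) and keypoints missing outright
#' are discarded and re-filled by linear interpolation between the nearest
#' accepted samples on either side; gaps at the bout edges are filled by the
#' nearest accepted value. Accepted samples pass through unchanged.
#'
#' @param bout A single-track `walking_bout`.
#' @param conf_threshold Confidence gate in `[0, 1]` (default 0.4).
#' @return A `pose_trajectory`: tibble with columns `frame`, `time_s`,
#'   `keypoint`, `x`, `y`, `imputed` (logical, `TRUE` exactly where the
#'   sample was gated or missing), carrying the bout metadata as attributes.
#'   No missing coordinates remain.
#' @details A required keypoint (see [required_keypoints()]) with fewer than
#'   two accepted samples makes imputation meaningless; the bout is rejected
#'   with a classed error (`gaitvision_bout_rejected`). Non-required
#'   keypoints in that situation are dropped from the trajectory with a
#'   warning.
#' @export
threshold_and_impute <- function(bout, conf_threshold = 0.4) {
  if (!inherits(bout, "walking_bout")) {
    abort("`bout` must be a single-track walking_bout (see select_participant_track()).")
  }
  df <- as_tibble(bout)
  df$imputed <- df$confidence < conf_threshold | !is.finite(df$x) | !is.finite(df$y)

  pieces <- split(df, df$keypoint)
  dropped <- character()
  out <- lapply(pieces, function(kp) {
    kp <- kp[order(kp$frame), ]
    ok <- !kp$imputed
    if (sum(ok) < 2L) {
      if (kp$keypoint[1] %in% required_keypoints()) {
        abort(
          paste0(
            "Bout ", attr(bout, "bout_id"), ": required keypoint '",
            kp$keypoint[1], "' has ", sum(ok), " accepted sample(s) at ",
            "confidence threshold ", conf_threshold, "; bout rejected."
          ),
          class = "gaitvision_bout_rejected"
        )
      }
      dropped <<- c(dropped, kp$keypoint[1])
      return(NULL)
    }
    kp$x[!ok] <- NA_real_
    kp$y[!ok] <- NA_real_
    kp$x <- zoo::na.approx(kp$x, x = kp$frame, na.rm = FALSE, rule = 2)
    kp$y <- zoo::na.approx(kp$y, x = kp$frame, na.rm = FALSE, rule = 2)
    kp
  })
  if (length(dropped)) {
    warn(paste0(
      "Dropped keypoint(s) with <2 accepted samples: ",
      paste(sort(dropped), collapse = ", ")
    ))
  }
  res <- bind_rows(out)
  res <- arrange(res[, c("frame", "time_s", "keypoint", "x", "y", "imputed")],
                 .data$frame, .data$keypoint)
  new_trajectory(res, bout, conf_threshold = conf_threshold)
}

new_trajectory <- function(df, template, conf_threshold = NA_real_) {
  out <- as_tibble(df)
  for (a in POSE_META) attr(out, a) <- attr(template, a)
  attr(out, "flags") <- bout_flags(template)
  attr(out, "conf_threshold") <-
    attr(template, "conf_threshold") %||% conf_threshold
  class(out) <- unique(c("pose_trajectory", class(out)))
  out
}

#' Fraction of imputed samples in a trajectory
#'
#' @param traj A `pose_trajectory`.
#' @param by Optionally `"keypoint"` for a per-keypoint breakdown.
#' @return A single fraction, or a tibble when `by = "keypoint"`.
#' @export
imputed_fraction <- function(traj, by = NULL) {
  if (identical(by, "keypoint")) {
    traj |>
      group_by(.data$keypoint) |>
      summarise(imputed_fraction = mean(.data$imputed), .groups = "drop")
  } else {
    mean(traj$imputed)
  }
}

butter_design <- function(fs, cutoff_hz, order) {
  if (fs <= 2 * cutoff_hz) {
    abort(sprintf(
      "Sampling rate %g Hz cannot support a %g Hz low-pass cutoff (need fs > 2*cutoff).",
      fs, cutoff_hz
    ))
  }
  signal::butter(order, cutoff_hz / (fs / 2), type = "low")
}

filter_steady <- function(b, a, x) {
  k <- length(a) - 1L
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], k), init.y = rep(x[1], k)))
}

#' Low-pass Butterworth filtering of a series
#'
#' Applies a low-pass Butterworth filter of the given order and cutoff.
#' The default is zero-phase: the filter runs forward and backward so events
#' (e.g. foot strikes) are not delayed, at the cost of doubling the
#' effective order. Edge transients are controlled by odd-reflection padding
#' with steady-state initial conditions, so a constant series passes through
#' unchanged (unit DC gain).
#'
#' @param x Numeric series (finite).
#' @param fs Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Cutoff frequency in Hz (default 4, suited to gait
#'   kinematics at 30 fps).
#' @param order Filter order (default 2).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return The filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff_hz = 4, order = 2, zero_phase = TRUE) {
  if (!all(is.finite(x))) abort("`x` must be finite; impute before filtering.")
  bf <- butter_design(fs, cutoff_hz, order)
  b <- bf$b
  a <- bf$a
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= padlen) {
    abort(
      sprintf(
        "Series of length %d is shorter than the filter warm-up length (%d); bout rejected.",
        n, padlen + 1L
      ),
      class = "gaitvision_bout_rejected"
    )
  }
  if (!zero_phase) {
    return(filter_steady(b, a, x))
  }
  # odd reflection about the end samples keeps slope continuity at the edges
  front <- 2 * x[1] - x[(padlen + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(front, x, back)
  y <- filter_steady(b, a, ext)
  y <- rev(filter_steady(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Low-pass filter every keypoint trajectory in a bout
#'
#' @param traj A `pose_trajectory` from [threshold_and_impute()].
#' @inheritParams lowpass
#' @return The trajectory with `x` and `y` filtered per keypoint.
#' @export
filter_trajectory <- function(traj, cutoff_hz = 4, order = 2,
                              zero_phase = TRUE) {
  fs <- bout_fps(traj)
  out <- traj |>
    group_by(.data$keypoint) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(
      x = lowpass(.data$x, fs, cutoff_hz, order, zero_phase),
      y = lowpass(.data$y, fs, cutoff_hz, order, zero_phase)
    ) |>
    ungroup() |>
    arrange(.data$frame, .data$keypoint)
  new_trajectory(out, traj)
}

kp_wide <- function(traj, keypoints) {
  traj[traj$keypoint %in% keypoints, c("frame", "time_s", "keypoint", "x", "y")] |>
    tidyr::pivot_wider(names_from = "keypoint", values_from = c("x", "y")) |>
    arrange(.data$frame)
}

#' Hip-span normalization context
#'
#' All pixel distances downstream are expressed in units of the mediolateral
#' hip span — the pixel distance between the left and right hip keypoints —
#' which removes the perspective scale of a walker approaching the camera.
#'
#' @param traj A `pose_trajectory` (imputed, ideally filtered).
#' @param policy `"per_frame"` (default): divide by the span of the same
#'   frame; `"bout_median"`: divide by the bout's median span (more robust
#'   when the span collapses in single frames).
#' @param floor_px Spans at or below this floor (default 1 px) are treated as
#'   unusable; the affected frames are dropped from whichever statistic is
#'   being normalized.
#' @return A `norm_context`: list with per-frame `hip_span` (named by frame),
#'   `policy`, `floor_px`, and `reference` (the bout-median span).
#' @export
normalization_context <- function(traj, policy = c("per_frame", "bout_median"),
                                  floor_px = 1) {
  policy <- match.arg(policy)
  hips <- kp_wide(traj, c("left_hip", "right_hip"))
  span <- sqrt((hips$x_left_hip - hips$x_right_hip)^2 +
                 (hips$y_left_hip - hips$y_right_hip)^2)
  names(span) <- hips$frame
  usable <- span[span > floor_px]
  if (!length(usable)) {
    abort("Hip span is at or below the floor in every frame; cannot normalize.",
          class = "gaitvision_bout_rejected")
  }
  structure(
    list(hip_span = span, policy = policy, floor_px = floor_px,
         reference = median(usable), frames = hips$frame),
    class = "norm_context"
  )
}

span_at <- function(context, frame) {
  s <- if (context$policy == "bout_median") {
    rep(context$reference, length(frame))
  } else {
    unname(context$hip_span[as.character(frame)])
  }
  s[!is.na(s) & s <= context$floor_px] <- NA_real_
  s
}

#' Normalize a pixel distance by the hip span
#'
#' @param distance_px Pixel distance(s).
#' @param context A `norm_context` from [normalization_context()].
#' @param frame Frame index (0-based) at which each distance was measured;
#'   recycled against `distance_px`.
#' @return Dimensionless distance(s) in hip-span units; `NA` where the hip
#'   span at that frame was at or below the floor (those frames are dropped
#'   from downstream statistics).
#' @export
normalize_distance <- function(distance_px, context, frame) {
  distance_px / span_at(context, frame)
}
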