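#' Per-bout gait variables
#'
#' Seven gait variables are computed per walking bout, all either temporal or
#' normalized to the mediolateral hip span (so they are dimensionless and
#' insensitive to camera distance): cadence (steps/min), step-time symmetry
#' index, step-time coefficient of variation, average and CV of step width,
#' and average and minimum estimated margin of stability (eMOS).
#'
#' @name gait-features
NULL

#' @rdname gait-features
#' @return `gait_feature_names()`: the seven feature column names.
#' @export
gait_feature_names <- function() {
  c("cadence", "si_step_time", "cv_step_time",
    "avg_step_width", "cv_step_width", "avg_emos", "min_emos")
}

#' Cadence in steps per minute
#'
#' Total number of foot strikes (both feet) divided by the bout duration in
#' minutes.
#'
#' @param events Strike table from [foot_strikes()], or an integer strike
#'   count.
#' @param duration_s Bout duration in seconds.
#' @return Steps per minute.
#' @export
cadence <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  n <- if (is.numeric(events)) events else nrow(events)
  n / (duration_s / 60)
}

#' Symmetry index of step timing
#'
#' The absolute difference between the total step time attributed to each
#' foot, divided by half of the total: `|T_L - T_R| / ((T_L + T_R) / 2)`.
#' 0 is perfectly symmetric timing; the value is bounded by 2.
#'
#' @param steps Step table from [step_times()].
#' @param total_s Denominator total time. Default `NULL` uses the attributed
#'   step time `T_L + T_R`; pass the bout duration to use wall-clock time
#'   instead.
#' @return Dimensionless symmetry index, or `NA` when either foot has no
#'   attributed step.
#' @export
symmetry_index <- function(steps, total_s = NULL) {
  pf <- per_foot_time(steps)
  if (any(pf <= 0)) {
    warn("Symmetry index undefined: a foot has no attributed steps.")
    return(NA_real_)
  }
  total <- total_s %||% sum(pf)
  abs(pf[["left"]] - pf[["right"]]) / (total / 2)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values Numeric vector.
#' @return `sd(values)/mean(values)`; `NA` with fewer than 2 values or a
#'   non-positive mean.
#' @export
cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  sd(values) / m
}

step_width_series <- function(traj, context) {
  w <- kp_wide(traj, c("left_ankle", "right_ankle"))
  tibble(
    frame = w$frame,
    time_s = w$time_s,
    width = normalize_distance(abs(w$x_left_ankle - w$x_right_ankle),
                               context, w$frame)
  )
}

#' Average step width in hip-span units
#'
#' Per frame, the horizontal (image-x) pixel distance between the two ankle
#' keypoints divided by that frame's hip span; averaged over frames. Frames
#' whose hip span is at or below the floor are dropped.
#'
#' @param traj A filtered `pose_trajectory`.
#' @param context A `norm_context` from [normalization_context()].
#' @return Mean normalized step width, or `NA` if no frame is usable.
#' @export
avg_step_width <- function(traj, context) {
  w <- step_width_series(traj, context)$width
  if (all(is.na(w))) return(NA_real_)
  mean(w, na.rm = TRUE)
}

#' Step width sampled at each foot strike
#'
#' One normalized ankle-separation value per merged strike frame; feeding
#' these to [cv()] gives the step-width CV on a per-step sampling unit,
#' matching how the step-time CV is formed.
#'
#' @inheritParams avg_step_width
#' @param events Strike table from [foot_strikes()].
#' @return Numeric vector of widths (one per strike; `NA` entries dropped).
#' @export
step_widths_per_step <- function(traj, events, context) {
  ws <- step_width_series(traj, context)
  out <- ws$width[match(events$frame, ws$frame)]
  out[!is.na(out)]
}

#' Leg length in hip-span units
#'
#' For each foot, the normalized Euclidean distance from the same-side hip to
#' the ankle, sampled at that foot's strike frames and averaged; the two
#' per-foot means are then averaged. Enters the extrapolated-centre-of-mass
#' construction as the pendulum length.
#'
#' @inheritParams step_widths_per_step
#' @return Normalized leg length; when a foot has no strikes the other
#'   foot's mean is used (with a message); `NA` when neither foot has any.
#' @export
leg_length_estimate <- function(traj, events, context) {
  per_foot <- vapply(c("left", "right"), function(foot) {
    frames <- events$frame[events$foot == foot]
    if (!length(frames)) return(NA_real_)
    w <- kp_wide(traj, c(paste0(foot, "_hip"), paste0(foot, "_ankle")))
    w <- w[w$frame %in% frames, ]
    d <- sqrt((w[[paste0("x_", foot, "_hip")]] - w[[paste0("x_", foot, "_ankle")]])^2 +
                (w[[paste0("y_", foot, "_hip")]] - w[[paste0("y_", foot, "_ankle")]])^2)
    mean(normalize_distance(d, context, w$frame), na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(per_foot))) return(NA_real_)
  if (any(is.na(per_foot))) {
    inform("One foot has no strikes; using the other foot's mean leg length.")
    return(per_foot[!is.na(per_foot)][[1]])
  }
  mean(per_foot)
}

#' Estimated centre of mass trajectory
#'
#' The eCOM is the midpoint of the two hip keypoints. Its mediolateral
#' velocity is computed by the same central-difference scheme used for ankle
#' velocities and expressed in hip-span units per second (pixel velocity
#' divided by the frame's hip span), which keeps it invariant to camera
#' scale and translation.
#'
#' @inheritParams avg_step_width
#' @return A tibble with `frame`, `time_s`, `ecom_x`, `ecom_y` (px), `span`
#'   (px, `NA` at or below the floor) and `v_norm` (hip-span units/s).
#' @export
ecom_series <- function(traj, context) {
  fs <- bout_fps(traj)
  hips <- kp_wide(traj, c("left_hip", "right_hip"))
  ecom_x <- (hips$x_left_hip + hips$x_right_hip) / 2
  ecom_y <- (hips$y_left_hip + hips$y_right_hip) / 2
  span <- span_at(context, hips$frame)
  tibble(
    frame = hips$frame,
    time_s = hips$time_s,
    ecom_x = ecom_x,
    ecom_y = ecom_y,
    span = span,
    v_norm = finite_diff(ecom_x, fs) / span
  )
}

#' Extrapolated centre of mass
#'
#' The inverted-pendulum extrapolation adds to the eCOM its velocity scaled
#' by the pendulum eigenfrequency: `eXCOM = eCOM + v / sqrt(g / l)`, with
#' everything in hip-span units (`l` is the normalized leg length, and `g`
#' enters with the same normalized length, mirroring the unitless relative
#' construction of the underlying stability measure).
#'
#' @param com eCOM table from [ecom_series()].
#' @param leg_length Normalized leg length from [leg_length_estimate()].
#' @param g Gravitational constant (default 9.81).
#' @return `com` with two added columns: `excom_dx` (the velocity offset
#'   `v_norm / sqrt(g / leg_length)`, hip-span units) and `excom_x_norm`
#'   (`ecom_x / span + excom_dx`). At zero velocity the eXCOM equals the
#'   eCOM.
#' @export
excom_series <- function(com, leg_length, g = 9.81) {
  stopifnot(leg_length > 0, g > 0)
  com$excom_dx <- com$v_norm / sqrt(g / leg_length)
  com$excom_x_norm <- com$ecom_x / com$span + com$excom_dx
  com
}

#' Estimated margin of stability
#'
#' Per frame, the signed normalized horizontal distance from the eXCOM to
#' the stance-foot ankle, with the sign chosen positive when the stance
#' ankle lies lateral of the eXCOM (further from the body midline, taken as
#' the eCOM). `avg_emos` averages this over every frame at or after the
#' first strike; `min_emos` averages, over steps (intervals between
#' consecutive merged strikes), each step's minimum.
#'
#' @inheritParams step_widths_per_step
#' @param g Gravitational constant (default 9.81).
#' @param leg_length Normalized leg length; computed via
#'   [leg_length_estimate()] when `NULL`.
#' @param com eCOM table; computed via [ecom_series()] when `NULL`.
#' @return A list: `avg_emos`, `min_emos`, and `frames` (tibble of `frame`,
#'   `time_s`, `stance`, `m` with the per-frame signed margin).
#' @export
emos <- function(traj, events, context, g = 9.81,
                 leg_length = NULL, com = NULL) {
  if (nrow(events) == 0L) {
    abort("No foot strikes; eMOS undefined.", class = "gaitvision_bout_rejected")
  }
  leg_length <- leg_length %||% leg_length_estimate(traj, events, context)
  com <- com %||% ecom_series(traj, context)
  com <- excom_series(com, leg_length = leg_length, g = g)

  ankles <- kp_wide(traj, c("left_ankle", "right_ankle"))
  df <- inner_join(com, ankles[, c("frame", "x_left_ankle", "x_right_ankle")],
                   by = "frame")
  df$stance <- stance_foot(df$time_s, events)
  ankle_x <- ifelse(df$stance == "left", df$x_left_ankle, df$x_right_ankle)
  lat_sign <- sign(ankle_x - df$ecom_x)
  lat_sign[lat_sign == 0] <- 1
  df$m <- lat_sign * ((ankle_x - df$ecom_x) / df$span - df$excom_dx)

  first_strike <- min(events$time_s)
  use <- df[df$time_s >= first_strike & !is.na(df$m), ]
  avg_emos <- if (nrow(use)) mean(use$m) else NA_real_

  steps <- step_times(events)
  min_emos <- NA_real_
  if (nrow(steps)) {
    step_idx <- findInterval(use$time_s, steps$start_s)
    in_step <- step_idx >= 1L & use$time_s < max(steps$end_s)
    if (any(in_step)) {
      mins <- tapply(use$m[in_step], step_idx[in_step], min)
      min_emos <- mean(mins)
    }
  }
  list(
    avg_emos = avg_emos, min_emos = min_emos,
    frames = df[, c("frame", "time_s", "stance", "m")]
  )
}

bout_reject <- function(bout, reason, detail = reason) {
  abort(
    paste0("Bout ", attr(bout, "bout_id"), " rejected: ", detail),
    class = "gaitvision_bout_rejected",
    reason = reason
  )
}

#' Extract the seven gait variables from one walking bout
#'
#' Runs the full per-bout chain: confidence gating with linear imputation,
#' zero-phase low-pass filtering, hip-span normalization, foot-strike
#' detection, and the seven feature computations. Bouts carrying manual
#' exclusion flags or yielding fewer than `config$min_strikes` foot strikes
#' are rejected with a classed error (`gaitvision_bout_rejected`) whose
#' `reason` field feeds the pipeline's discard log.
#'
#' @param bout A `walking_bout`.
#' @param config Pipeline parameters, see [pipeline_config()].
#' @return A one-row tibble: `bout_id`, `participant_id`, `recorded_at`, the
#'   seven features (a feature whose preconditions fail, e.g. the symmetry
#'   index when one foot has no attributed step, is `NA`, never zero),
#'   `n_steps` (total strikes) and `duration_s`.
#' @export
extract_features <- function(bout, config = pipeline_config()) {
  manual <- intersect(bout_flags(bout), c("handrail", "turned_around", "occluded"))
  if (length(manual)) {
    bout_reject(bout, reason = manual[1],
                detail = paste0("manual exclusion flag(s): ",
                                paste(manual, collapse = ", ")))
  }
  traj <- threshold_and_impute(bout, conf_threshold = config$conf_threshold)
  traj <- filter_trajectory(traj, cutoff_hz = config$cutoff_hz,
                            order = config$filter_order,
                            zero_phase = config$zero_phase)
  context <- normalization_context(traj, policy = config$span_policy,
                                   floor_px = config$hip_span_floor_px)
  events <- foot_strikes(traj, config = config)
  if (nrow(events) < config$min_strikes) {
    bout_reject(bout, reason = "too_few_steps",
                detail = paste0(nrow(events), " foot strikes detected (< ",
                                config$min_strikes, ")"))
  }
  duration_s <- bout_duration(bout)
  steps <- step_times(events)
  pf <- per_foot_time(steps)
  si <- if (all(pf > 0)) symmetry_index(steps) else NA_real_
  widths <- step_widths_per_step(traj, events, context)
  mos <- emos(traj, events, context, g = config$g)

  tibble(
    bout_id = attr(bout, "bout_id"),
    participant_id = attr(bout, "participant_id"),
    recorded_at = attr(bout, "recorded_at"),
    cadence = cadence(events, duration_s),
    si_step_time = si,
    cv_step_time = cv(steps$duration_s),
    avg_step_width = avg_step_width(traj, context),
    cv_step_width = cv(widths),
    avg_emos = mos$avg_emos,
    min_emos = mos$min_emos,
    n_steps = nrow(events),
    duration_s = duration_s
  )
}

#' Baseline gait variables per participant
#'
#' Averages each feature over a participant's retained bouts recorded within
#' `window_days` of enrollment (inclusive), yielding the participant's
#' baseline gait variables.
#'
#' @param features Per-bout feature table (rows as returned by
#'   [extract_features()]).
#' @param enrollment Tibble with `participant_id` and `enrollment_date`
#'   (ISO date string or `Date`).
#' @param window_days Baseline window length in days (default 14).
#' @return A tibble with one row per participant: the mean of each feature
#'   over in-window bouts (`NA` feature values are dropped from their
#'   feature's mean) and `n_bouts`. Participants with no in-window bout are
#'   omitted with a message.
#' @export
baseline_aggregate <- function(features, enrollment, window_days = 14) {
  enr <- mutate(enrollment, enrollment_date = as.Date(.data$enrollment_date))
  df <- features |>
    mutate(recorded_date = as.Date(.data$recorded_at)) |>
    inner_join(enr, by = "participant_id") |>
    filter(
      .data$recorded_date >= .data$enrollment_date,
      .data$recorded_date <= .data$enrollment_date + window_days
    )
  lost <- setdiff(unique(features$participant_id), unique(df$participant_id))
  if (length(lost)) {
    inform(paste0(
      "No bouts within the ", window_days, "-day baseline window for: ",
      paste(lost, collapse = ", ")
    ))
  }
  df |>
    group_by(.data$participant_id) |>
    summarise(
      across(all_of(gait_feature_names()), ~ mean(.x, na.rm = TRUE)),
      n_bouts = n(),
      .groups = "drop"
    )
}
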