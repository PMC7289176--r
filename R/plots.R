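#' Plot a walking bout's ankle trajectories
#'
#' Vertical ankle keypoint movement over time (y flipped so up is up), the
#' raw signal behind foot-strike detection.
#'
#' @param object A `walking_bout` or `pose_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.walking_bout <- function(object, ...) {
  df <- object[object$keypoint %in% c("left_ankle", "right_ankle"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = -.data$y,
                                   colour = .data$keypoint)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = "Vertical position (px, up-positive)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.walking_bout
#' @export
autoplot.pose_trajectory <- autoplot.walking_bout

#' Ankle vertical velocity with detected foot strikes
#'
#' @param traj A filtered `pose_trajectory`.
#' @param events Strike table from [foot_strikes()].
#' @return A ggplot of each ankle's up-positive vertical velocity with
#'   strikes marked.
#' @export
plot_foot_strikes <- function(traj, events) {
  fs <- bout_fps(traj)
  vel <- traj |>
    filter(.data$keypoint %in% c("left_ankle", "right_ankle")) |>
    group_by(.data$keypoint) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(velocity = vertical_velocity(.data$y, fs),
           foot = sub("_ankle", "", .data$keypoint)) |>
    ungroup()
  ggplot2::ggplot(vel, ggplot2::aes(x = .data$time_s, y = .data$velocity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$time_s),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~foot, ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = "Ankle vertical velocity (px/s, up+)") +
    ggplot2::theme_minimal()
}

#' Margin-of-stability trace
#'
#' @param mos Result of [emos()].
#' @return A ggplot of the per-frame signed margin, coloured by stance foot.
#' @export
plot_emos <- function(mos) {
  ggplot2::ggplot(mos$frames,
                  ggplot2::aes(x = .data$time_s, y = .data$m,
                               colour = .data$stance)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time (s)", y = "eMOS (hip-span units)",
                  colour = "Stance foot") +
    ggplot2::theme_minimal()
}
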