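#' PCKh keypoint-accuracy evaluation
#'
#' Percentage of Correct Keypoints with the head-normalized threshold
#' (PCKh): a predicted keypoint is correct when its Euclidean distance to
#' the manual annotation is at most `alpha` times the head-segment length of
#' that image (distance from the annotated `head_top` to `neck`); a point
#' exactly at the threshold counts as correct. `alpha = 0.5` is the standard
#' PCKh@0.5.
#'
#' @param predictions Tibble with `image_id`, `keypoint`, `x`, `y` and
#'   optionally `confidence`.
#' @param annotations Tibble with `image_id`, `keypoint`, `x`, `y` (manual
#'   ground truth).
#' @param alpha Threshold multiplier on the head-segment length (default
#'   0.5).
#' @param subsets Named list of keypoint subsets to score; `NULL` entries
#'   mean all annotated keypoints. The default scores all keypoints, the two
#'   ankles, and the two hips.
#' @param head_lengths Optional tibble `image_id`, `head_length` overriding
#'   the per-image head segment computed from the annotations.
#' @return A `pck_report` tibble: one row per subset with `subset`, `cutoff`
#'   (confidence cutoff applied, 0 here), `pck`, `n_evaluated`,
#'   `n_discarded`, `n_skipped` (predictions with no matching annotation).
#' @export
pckh <- function(predictions, annotations, alpha = 0.5,
                 subsets = list(all = NULL,
                                ankles = c("left_ankle", "right_ankle"),
                                hips = c("left_hip", "right_hip")),
                 head_lengths = NULL) {
  if (is.null(head_lengths)) {
    head_lengths <- head_segment_lengths(annotations)
  }
  if (any(!is.finite(head_lengths$head_length) | head_lengths$head_length <= 0)) {
    abort("Non-positive head-segment length; check head_top/neck annotations.")
  }
  scored <- predictions |>
    inner_join(annotations, by = c("image_id", "keypoint"),
               suffix = c("", "_ann")) |>
    inner_join(head_lengths, by = "image_id") |>
    mutate(
      dist = sqrt((.data$x - .data$x_ann)^2 + (.data$y - .data$y_ann)^2),
      correct = .data$dist <= alpha * .data$head_length
    )
  n_skipped <- nrow(predictions) - nrow(scored)
  rows <- purrr::imap(subsets, function(kps, nm) {
    sub <- if (is.null(kps)) scored else scored[scored$keypoint %in% kps, ]
    ok <- is.finite(sub$dist)
    tibble(
      subset = nm,
      cutoff = 0,
      pck = if (sum(ok)) mean(sub$correct[ok]) else NA_real_,
      n_evaluated = sum(ok),
      n_discarded = 0L,
      n_skipped = n_skipped
    )
  })
  out <- bind_rows(rows)
  class(out) <- unique(c("pck_report", class(out)))
  out
}

#' Head-segment lengths from annotations
#'
#' @param annotations Annotation tibble containing `head_top` and `neck`
#'   rows per image.
#' @return Tibble `image_id`, `head_length` (px).
#' @export
head_segment_lengths <- function(annotations) {
  w <- annotations |>
    filter(.data$keypoint %in% c("head_top", "neck")) |>
    tidyr::pivot_wider(id_cols = "image_id", names_from = "keypoint",
                       values_from = c("x", "y"))
  if (!all(c("x_head_top", "x_neck") %in% names(w))) {
    abort("Annotations must include head_top and neck for every image (or supply head_lengths).")
  }
  tibble(
    image_id = w$image_id,
    head_length = sqrt((w$x_head_top - w$x_neck)^2 + (w$y_head_top - w$y_neck)^2)
  )
}

#' PCKh under confidence-score cutoffs
#'
#' Repeats the PCKh evaluation after discarding predictions whose confidence
#' falls strictly below each cutoff, reporting how the accuracy/coverage
#' trade-off moves: higher cutoffs discard more keypoints but tend to raise
#' the PCKh of the remainder.
#'
#' @inheritParams pckh
#' @param cutoffs Confidence cutoffs to sweep (default 0.2, 0.4, 0.6, 0.8).
#' @return A `pck_report` tibble with one row per (cutoff, subset);
#'   `n_discarded` counts predictions dropped by the cutoff (within the
#'   subset) and `discarded_fraction` their share; `pck` is `NA` when a
#'   cutoff discards everything.
#' @export
confidence_sweep <- function(predictions, annotations,
                             cutoffs = c(0.2, 0.4, 0.6, 0.8), alpha = 0.5,
                             subsets = list(all = NULL,
                                            ankles = c("left_ankle", "right_ankle")),
                             head_lengths = NULL) {
  if (!"confidence" %in% names(predictions)) {
    abort("`predictions` must carry a `confidence` column for a cutoff sweep.")
  }
  rows <- purrr::map(cutoffs, function(ct) {
    keep <- predictions$confidence >= ct
    counts <- purrr::imap(subsets, function(kps, nm) {
      in_sub <- if (is.null(kps)) rep(TRUE, nrow(predictions)) else
        predictions$keypoint %in% kps
      sum(in_sub & !keep)
    })
    totals <- purrr::imap(subsets, function(kps, nm) {
      if (is.null(kps)) nrow(predictions) else sum(predictions$keypoint %in% kps)
    })
    rep_ct <- pckh(predictions[keep, , drop = FALSE], annotations,
                   alpha = alpha, subsets = subsets,
                   head_lengths = head_lengths)
    rep_ct$cutoff <- ct
    rep_ct$n_discarded <- unname(unlist(counts)[rep_ct$subset])
    rep_ct$discarded_fraction <-
      unname(rep_ct$n_discarded / unlist(totals)[rep_ct$subset])
    rep_ct
  })
  out <- bind_rows(rows)
  class(out) <- unique(c("pck_report", class(out)))
  out
}

#' @export
#' @rdname pckh
#' @param object A `pck_report`.
#' @param ... Unused.
autoplot.pck_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cutoff, y = .data$pck,
                               colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Confidence cutoff", y = "PCKh",
                  colour = "Keypoints") +
    ggplot2::theme_minimal()
}
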