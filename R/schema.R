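#' Keypoint schemas
#'
#' A keypoint schema is an ordered character vector of keypoint labels. The
#' downstream gait math needs six labels to be present: both hips (hip-span
#' normalization and the estimated centre of mass), both ankles (foot-strike
#' detection, step width, margin of stability) and the head segment endpoints
#' (`head_top`, `neck`) used by PCKh verification. The remaining labels are
#' configurable; [default_keypoints()] ships a 13-label skeleton typical of
#' MPII-style pose models.
#'
#' @return A character vector of keypoint labels.
#' @examples
#' default_keypoints()
#' required_keypoints()
#' @export
default_keypoints <- function() {
  c(
    "head_top", "neck", "thorax",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle"
  )
}

#' @rdname default_keypoints
#' @export
required_keypoints <- function() {
  c("left_hip", "right_hip", "left_ankle", "right_ankle", "head_top", "neck")
}

check_schema <- function(schema) {
  if (!is.character(schema) || length(schema) < 1L || anyDuplicated(schema)) {
    abort("`schema` must be a character vector of unique keypoint labels.")
  }
  missing_req <- setdiff(required_keypoints(), schema)
  if (length(missing_req) > 0L) {
    abort(paste0(
      "Schema is missing required keypoint label(s): ",
      paste(missing_req, collapse = ", ")
    ))
  }
  invisible(schema)
}
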