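#' Pose-frame tables and walking bouts
#'
#' Keypoint sequences are held in long tibbles with one row per
#' (frame, track, keypoint): columns `frame` (0-based integer), `time_s`
#' (`frame / fps`), `track` (character id of a detected person), `keypoint`
#' (label from the schema), `x`, `y` (pixel coordinates, `y` increasing
#' downward; `NA` when the detector reported nothing) and `confidence`
#' (detector score in `[0, 1]`, 0 for missing points). Bout-level metadata
#' (`fps`, `bout_id`, `participant_id`, `recorded_at`, the schema, and for
#' single-track bouts the exclusion `flags`) travels as attributes.
#'
#' A *walking bout* is a pose-frame table restricted to exactly one track.
#' All "vertical" computations downstream negate `y` so that up is positive.
#'
#' @name pose-frames
NULL

POSE_META <- c("fps", "schema", "bout_id", "participant_id", "recorded_at")

new_pose_frames <- function(df, fps, schema,
                            bout_id = NA_character_,
                            participant_id = NA_character_,
                            recorded_at = NA_character_) {
  out <- as_tibble(df)
  attr(out, "fps") <- fps
  attr(out, "schema") <- schema
  attr(out, "bout_id") <- bout_id
  attr(out, "participant_id") <- participant_id
  attr(out, "recorded_at") <- recorded_at
  class(out) <- unique(c("pose_frames", class(out)))
  out
}

new_walking_bout <- function(df, template, flags = character()) {
  out <- new_pose_frames(
    df,
    fps = attr(template, "fps"),
    schema = attr(template, "schema"),
    bout_id = attr(template, "bout_id"),
    participant_id = attr(template, "participant_id"),
    recorded_at = attr(template, "recorded_at")
  )
  attr(out, "flags") <- unique(as.character(flags))
  class(out) <- unique(c("walking_bout", class(out)))
  out
}

#' Bout metadata accessors
#'
#' @param x A pose-frame table or walking bout.
#' @return `bout_fps()` the sampling rate in Hz; `bout_duration()` the bout
#'   length in seconds (`n_frames / fps`); `bout_flags()` the character vector
#'   of exclusion flags; `bout_retained()` `TRUE` when no exclusion flag is
#'   set.
#' @export
bout_fps <- function(x) attr(x, "fps")

#' @rdname bout_fps
#' @export
bout_duration <- function(x) {
  n_frames <- length(unique(x$frame))
  n_frames / bout_fps(x)
}

#' @rdname bout_fps
#' @export
bout_flags <- function(x) attr(x, "flags") %||% character()

#' @rdname bout_fps
#' @export
bout_retained <- function(x) length(bout_flags(x)) == 0L

#' Read a pose-keypoint JSON file
#'
#' The on-disk dialect mirrors per-frame output of 2D pose estimators: either
#' a top-level object `{"fps": .., "bout_id": .., "frames": [...]}` or a bare
#' array of frame objects. Each frame object is
#' `{"frame": i, "people": [{"id": "t1", "keypoints": {"left_hip": [x, y, c],
#' ...}}]}` with keypoints stored as `[x, y, confidence]` triples keyed by
#' label. `null` coordinates denote a missing detection.
#'
#' Keypoint labels not in `schema` are dropped with a warning; schema labels
#' absent from a person's map are materialised as missing points with
#' confidence 0.
#'
#' @param path Path to a JSON file.
#' @param schema Character vector of keypoint labels (see
#'   [default_keypoints()]).
#' @param fps Frames per second; required when the file carries no `fps`
#'   field.
#' @return A pose-frame tibble (possibly multi-track); see [pose-frames].
#' @export
read_pose_json <- function(path, schema = default_keypoints(), fps = NULL) {
  check_schema(schema)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("Malformed pose JSON in '", path, "': ", conditionMessage(e)))
    }
  )
  if (is.null(names(raw))) {
    frames_raw <- raw
    meta <- list()
  } else {
    frames_raw <- raw$frames
    meta <- raw[setdiff(names(raw), "frames")]
  }
  if (is.null(frames_raw) || length(frames_raw) == 0L) {
    abort(paste0("Pose JSON '", path, "' contains no frames."))
  }
  fps <- meta$fps %||% fps
  if (is.null(fps)) {
    abort(paste0(
      "No frame rate: '", path, "' carries no `fps` field and none was supplied."
    ))
  }

  dropped <- character()
  nk <- length(schema)
  frame_c <- list(); track_c <- list()
  x_c <- list(); y_c <- list(); conf_c <- list()
  k <- 0L
  for (i in seq_along(frames_raw)) {
    fr <- frames_raw[[i]]
    if (is.null(fr$frame)) {
      abort(paste0("Malformed pose JSON in '", path, "': frame ", i,
                   " has no `frame` index."))
    }
    idx <- as.integer(fr$frame)
    people <- fr$people %||% list()
    for (p in people) {
      pid <- as.character(p$id %||% "1")
      kps <- p$keypoints %||% list()
      extra <- setdiff(names(kps), schema)
      if (length(extra)) dropped <- union(dropped, extra)
      x <- y <- setNames(rep(NA_real_, nk), schema)
      conf <- setNames(rep(0, nk), schema)
      for (nm in intersect(names(kps), schema)) {
        triple <- kps[[nm]]
        x[nm] <- if (is.null(triple[[1]])) NA_real_ else as.numeric(triple[[1]])
        y[nm] <- if (is.null(triple[[2]])) NA_real_ else as.numeric(triple[[2]])
        conf[nm] <- if (length(triple) < 3L || is.null(triple[[3]])) 0 else
          as.numeric(triple[[3]])
      }
      k <- k + 1L
      frame_c[[k]] <- rep(idx, nk)
      track_c[[k]] <- rep(pid, nk)
      x_c[[k]] <- unname(x)
      y_c[[k]] <- unname(y)
      conf_c[[k]] <- unname(conf)
    }
  }
  if (length(dropped)) {
    warn(paste0(
      "Dropped keypoint label(s) not in schema: ",
      paste(sort(dropped), collapse = ", ")
    ))
  }
  if (k == 0L) {
    abort(paste0("Pose JSON '", path, "' lists frames but no tracked people."))
  }
  df <- tibble(
    frame = unlist(frame_c), track = unlist(track_c),
    keypoint = rep(schema, k),
    x = unlist(x_c), y = unlist(y_c), confidence = unlist(conf_c)
  )
  df$time_s <- df$frame / fps
  df <- df[, c("frame", "time_s", "track", "keypoint", "x", "y", "confidence")]
  df <- arrange(df, .data$frame, .data$track)
  new_pose_frames(
    df,
    fps = fps, schema = schema,
    bout_id = as.character(meta$bout_id %||% NA_character_),
    participant_id = as.character(meta$participant_id %||% NA_character_),
    recorded_at = as.character(meta$recorded_at %||% NA_character_)
  )
}

#' Write a pose-frame table to the JSON dialect
#'
#' Inverse of [read_pose_json()]; numbers are written with 17 significant
#' digits so coordinates round-trip exactly.
#'
#' @param x A pose-frame table or walking bout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(x, path) {
  fps <- bout_fps(x)
  df <- x[order(x$frame, x$track), ]
  num <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "null"
    out
  }
  str_or_null <- function(v) {
    if (is.null(v) || is.na(v)) "null" else paste0('"', v, '"')
  }
  kp_str <- sprintf('"%s":[%s,%s,%s]', df$keypoint, num(df$x), num(df$y),
                    num(df$confidence))
  grp <- cumsum(!duplicated(paste(df$frame, df$track)))
  person_kps <- vapply(split(kp_str, grp), paste, character(1), collapse = ",")
  firsts <- !duplicated(grp)
  person_str <- sprintf('{"id":"%s","keypoints":{%s}}',
                        df$track[firsts], person_kps)
  frame_of_person <- df$frame[firsts]
  fgrp <- cumsum(!duplicated(frame_of_person))
  frame_people <- vapply(split(person_str, fgrp), paste, character(1),
                         collapse = ",")
  frame_str <- sprintf('{"frame":%d,"people":[%s]}',
                       frame_of_person[!duplicated(frame_of_person)],
                       frame_people)
  doc <- sprintf(
    '{"bout_id":%s,"participant_id":%s,"recorded_at":%s,"fps":%s,"frames":[%s]}',
    str_or_null(attr(x, "bout_id")), str_or_null(attr(x, "participant_id")),
    str_or_null(attr(x, "recorded_at")), sprintf("%.17g", fps),
    paste(frame_str, collapse = ",")
  )
  writeLines(doc, path)
  invisible(path)
}

median_hip_span <- function(df) {
  hips <- tidyr::pivot_wider(
    df[df$keypoint %in% c("left_hip", "right_hip") & df$confidence > 0,
       c("frame", "keypoint", "x", "y")],
    names_from = "keypoint", values_from = c("x", "y")
  )
  if (!all(c("x_left_hip", "x_right_hip") %in% names(hips))) return(NA_real_)
  span <- sqrt((hips$x_left_hip - hips$x_right_hip)^2 +
                 (hips$y_left_hip - hips$y_right_hip)^2)
  span <- span[is.finite(span)]
  if (!length(span)) return(NA_real_)
  median(span)
}

#' Select the participant's track from a multi-person pose table
#'
#' Walking bouts are recorded as the participant passes a hallway camera,
#' often accompanied by staff; keypoints from other detected people must be
#' discarded before gait analysis. The default policy keeps the track with
#' the largest median pixel hip span, a proxy for the foreground (nearest)
#' person in the camera's perspective.
#'
#' @param pose A pose-frame table from [read_pose_json()] or
#'   [simulate_bout()].
#' @param policy `"largest_hip_span"` (default), `"most_frames"`, or
#'   `"explicit_id"`.
#' @param track_id Track id to keep when `policy = "explicit_id"`.
#' @param flags Optional character vector of manual exclusion flags to attach
#'   (`"handrail"`, `"turned_around"`, `"occluded"`).
#' @return A `walking_bout`: the same frame grid restricted to one track;
#'   frames where the selected track was not detected keep placeholder rows
#'   with all keypoints missing (confidence 0).
#' @export
select_participant_track <- function(pose,
                                     policy = c("largest_hip_span",
                                                "most_frames", "explicit_id"),
                                     track_id = NULL,
                                     flags = character()) {
  policy <- match.arg(policy)
  tracks <- unique(pose$track)
  if (length(tracks) == 0L) abort("No tracks present in any frame.")
  keep <- switch(policy,
    largest_hip_span = {
      spans <- vapply(tracks, function(tr) {
        median_hip_span(pose[pose$track == tr, ])
      }, numeric(1))
      if (all(is.na(spans))) tracks[1] else tracks[which.max(spans)]
    },
    most_frames = {
      counts <- vapply(tracks, function(tr) {
        length(unique(pose$frame[pose$track == tr]))
      }, integer(1))
      tracks[which.max(counts)]
    },
    explicit_id = {
      if (is.null(track_id)) abort("`track_id` is required for policy 'explicit_id'.")
      if (!track_id %in% tracks) {
        abort(paste0("Track '", track_id, "' not present in this recording."))
      }
      as.character(track_id)
    }
  )
  schema <- attr(pose, "schema")
  fps <- bout_fps(pose)
  all_frames <- sort(unique(pose$frame))
  sel <- pose[pose$track == keep, ]
  grid <- tidyr::expand_grid(frame = all_frames, keypoint = schema)
  out <- left_join(grid, sel[, c("frame", "keypoint", "x", "y", "confidence")],
                   by = c("frame", "keypoint"))
  out$confidence[is.na(out$confidence)] <- 0
  out$track <- keep
  out$time_s <- out$frame / fps
  out <- out[, c("frame", "time_s", "track", "keypoint", "x", "y", "confidence")]
  new_walking_bout(out, template = pose, flags = flags)
}

#' Quality-control a walking bout
#'
#' Flags a bout `too_few_steps` when fewer than `min_strikes` foot strikes
#' were detected over the whole recording; manual exclusion flags
#' (`handrail`, `turned_around`, `occluded`) are preserved and always exclude
#' the bout from feature aggregation regardless of step count. Keypoint data
#' are never modified, only the flag set.
#'
#' @param bout A `walking_bout`.
#' @param n_strikes Total number of detected foot strikes (both feet merged).
#'   When `NULL`, the default preprocessing and detection chain
#'   ([threshold_and_impute()] -> [filter_trajectory()] -> [foot_strikes()])
#'   is run to count them.
#' @param min_strikes Minimum strike count for retention (default 3; a bout
#'   with exactly 3 strikes is retained).
#' @param config Pipeline parameters used when `n_strikes` must be computed.
#' @return The bout with its `too_few_steps` flag updated.
#' @export
qc_bout <- function(bout, n_strikes = NULL, min_strikes = 3,
                    config = pipeline_config()) {
  if (is.null(n_strikes)) {
    n_strikes <- tryCatch({
      traj <- threshold_and_impute(bout, conf_threshold = config$conf_threshold)
      traj <- filter_trajectory(traj, cutoff_hz = config$cutoff_hz,
                                order = config$filter_order,
                                zero_phase = config$zero_phase)
      nrow(foot_strikes(traj, config = config))
    }, gaitvision_bout_rejected = function(e) 0L)
  }
  flags <- setdiff(bout_flags(bout), "too_few_steps")
  if (n_strikes < min_strikes) flags <- c(flags, "too_few_steps")
  attr(bout, "flags") <- flags
  bout
}

#' Read or write a bout manifest
#'
#' A manifest is a CSV with one row per recorded bout: `bout_id`,
#' `participant_id`, `recorded_at` (ISO date), `fps`, `path` (pose JSON file)
#' and `flags` (semicolon-separated manual exclusion flags, empty when none).
#'
#' @param path CSV path.
#' @return A tibble with the columns above; `flags` is kept as a character
#'   column (`parse_flags()` splits one entry into a vector).
#' @export
read_bout_manifest <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    bout_id = readr::col_character(),
    participant_id = readr::col_character(),
    recorded_at = readr::col_character(),
    fps = readr::col_double(),
    path = readr::col_character(),
    flags = readr::col_character()
  ))
}

#' @rdname read_bout_manifest
#' @param manifest A manifest tibble.
#' @export
write_bout_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname read_bout_manifest
#' @param flags A single manifest `flags` entry.
#' @export
parse_flags <- function(flags) {
  if (is.na(flags) || !nzchar(flags)) return(character())
  strsplit(flags, ";", fixed = TRUE)[[1]]
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf(
    "<walking_bout %s> participant %s, %d frames @ %g fps (%.2f s)%s\n",
    attr(x, "bout_id"), attr(x, "participant_id"),
    length(unique(x$frame)), bout_fps(x), bout_duration(x),
    if (length(bout_flags(x))) {
      paste0(", flags: ", paste(bout_flags(x), collapse = ", "))
    } else ""
  ))
  NextMethod()
}
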