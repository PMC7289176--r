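test_that("pose JSON round-trips a synthetic bout exactly", {
  sim <- simulate_bout(gait_sim_params(seed = 11, duration_s = 3,
                                       assistant = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_json(sim$pose, path)
  back <- read_pose_json(path)

  expect_identical(nrow(back), nrow(sim$pose))
  orig <- dplyr::arrange(as.data.frame(sim$pose), frame, track, keypoint)
  got <- dplyr::arrange(as.data.frame(back), frame, track, keypoint)
  expect_identical(got$x, orig$x)
  expect_identical(got$y, orig$y)
  expect_true(max(abs(got$confidence - orig$confidence)) <= 1e-9)
  expect_equal(bout_fps(back), bout_fps(sim$pose))
  expect_identical(attr(back, "bout_id"), attr(sim$pose, "bout_id"))
})

test_that("frames with several people keep one track entry each", {
  sim <- simulate_bout(gait_sim_params(seed = 2, duration_s = 2,
                                       assistant = TRUE))
  f0 <- sim$pose[sim$pose$frame == 0, ]
  expect_setequal(unique(f0$track), c("participant", "assistant"))
  expect_identical(nrow(f0), 2L * length(default_keypoints()))
})

test_that("keypoints absent from a frame are materialised as missing with confidence 0", {
  path <- withr::local_tempfile(fileext = ".json")
  kp <- list(left_hip = c(10, 20, 0.9), right_hip = c(30, 20, 0.8),
             left_ankle = c(12, 90, 0.9), head_top = c(20, 2, 0.9),
             neck = c(20, 10, 0.9))
  doc <- list(fps = 30, frames = list(list(
    frame = 0, people = list(list(id = "1", keypoints = kp))
  )))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  got <- read_pose_json(path)
  ra <- got[got$keypoint == "right_ankle", ]
  expect_identical(nrow(ra), 1L)
  expect_true(is.na(ra$x) && is.na(ra$y))
  expect_identical(ra$confidence, 0)
  # all 13 schema labels present even though only 5 were listed
  expect_setequal(got$keypoint, default_keypoints())
})

test_that("labels outside the schema are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".json")
  kp <- list(left_hip = c(10, 20, 1), right_hip = c(30, 20, 1),
             left_big_toe = c(1, 2, 1))
  doc <- list(fps = 30, frames = list(list(
    frame = 0, people = list(list(id = "1", keypoints = kp))
  )))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(got <- read_pose_json(path), "left_big_toe")
  expect_false("left_big_toe" %in% got$keypoint)
})

test_that("malformed or underspecified input produces informative errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(read_pose_json(bad), "Malformed", fixed = FALSE)

  no_fps <- withr::local_tempfile(fileext = ".json")
  doc <- list(list(frame = 0, people = list(list(
    id = "1", keypoints = list(left_hip = c(1, 2, 1))
  ))))
  jsonlite::write_json(doc, no_fps, auto_unbox = TRUE, digits = NA)
  expect_error(read_pose_json(no_fps), "fps")
  expect_s3_class(read_pose_json(no_fps, fps = 30), "pose_frames")
})

test_that("track selection follows the policy and is idempotent", {
  # two handcrafted tracks, hip spans 80 px vs 40 px
  mk <- function(track, span) {
    tibble::tibble(
      frame = rep(0:9, each = 2), time_s = rep(0:9, each = 2) / 30,
      track = track,
      keypoint = rep(c("left_hip", "right_hip"), 10),
      x = rep(c(0, span), 10), y = 100, confidence = 1
    )
  }
  pose <- gaitvision:::new_pose_frames(
    dplyr::bind_rows(mk("A", 80), mk("B", 40)),
    fps = 30, schema = default_keypoints(), bout_id = "two"
  )
  sel <- select_participant_track(pose, policy = "largest_hip_span")
  expect_identical(unique(sel$track), "A")
  # placeholders exist for all schema keypoints
  expect_setequal(sel$keypoint, default_keypoints())
  sel2 <- select_participant_track(sel, policy = "largest_hip_span")
  expect_identical(as.data.frame(sel2), as.data.frame(sel))

  expect_identical(
    unique(select_participant_track(pose, policy = "explicit_id",
                                    track_id = "B")$track), "B")
})

test_that("the participant is recovered next to a half-scale assistant track", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_bout(gait_sim_params(seed = s, duration_s = 4,
                                         assistant = TRUE))
    sel <- select_participant_track(sim$pose, policy = "largest_hip_span")
    unique(sel$track) == sim$truth$participant_track
  }, logical(1))
  expect_true(all(hits))
})

test_that("QC flags follow the 3-strike rule and never mutate keypoints", {
  bout <- toy_bout(30)
  flagged <- qc_bout(bout, n_strikes = 2)
  expect_true("too_few_steps" %in% bout_flags(flagged))
  kept <- qc_bout(bout, n_strikes = 3)
  expect_false("too_few_steps" %in% bout_flags(kept))
  expect_identical(as.data.frame(kept)[c("x", "y", "confidence")],
                   as.data.frame(bout)[c("x", "y", "confidence")])

  # a manual flag dominates regardless of strike count
  manual <- toy_bout(30, flags = "handrail")
  manual <- qc_bout(manual, n_strikes = 10)
  expect_false(bout_retained(manual))
  expect_error(extract_features(manual), class = "gaitvision_bout_rejected")
})

test_that("bout manifests round-trip through CSV", {
  m <- tibble::tibble(
    bout_id = c("b1", "b2"), participant_id = c("P01", "P01"),
    recorded_at = c("2020-01-02", "2020-01-03"), fps = c(30, 30),
    path = c("a.json", "b.json"), flags = c("", "handrail;occluded")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_bout_manifest(m, path)
  back <- read_bout_manifest(path)
  expect_identical(back$bout_id, m$bout_id)
  expect_identical(parse_flags(back$flags[2]), c("handrail", "occluded"))
  expect_identical(parse_flags(back$flags[1]), character())
})
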