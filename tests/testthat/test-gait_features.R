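test_that("cadence is strikes over duration in minutes", {
  expect_equal(cadence(20, 12), 100)
  expect_equal(cadence(0, 10), 0)
})

test_that("symmetry index follows its defining formula", {
  st <- tibble::tibble(foot = c("left", "right"), start_s = c(0, 6),
                       end_s = c(6, 10), duration_s = c(6, 4))
  expect_equal(symmetry_index(st), abs(6 - 4) / 5)
  sym <- tibble::tibble(foot = c("left", "right"), start_s = c(0, 1),
                        end_s = c(1, 2), duration_s = c(1, 1))
  expect_equal(symmetry_index(sym), 0)
  one_foot <- tibble::tibble(foot = "left", start_s = 0, end_s = 1,
                             duration_s = 1)
  expect_warning(si <- symmetry_index(one_foot), "undefined")
  expect_true(is.na(si))
})

test_that("CV uses the sample (n-1) standard deviation", {
  expect_equal(cv(rep(0.5, 10)), 0)
  expect_equal(cv(c(0.4, 0.6)), sd(c(0.4, 0.6)) / 0.5)
  expect_equal(cv(c(0.4, 0.6)), 0.2828427, tolerance = 1e-6)
  expect_true(is.na(cv(0.5)))
})

test_that("CV estimates recover a known generating CV", {
  set.seed(100)
  est <- replicate(500, cv(rnorm(20, mean = 1, sd = 0.1)))
  expect_lt(abs(mean(est) - 0.1), 0.02)
})

test_that("step width is the normalized horizontal ankle separation", {
  # ankles separated horizontally by exactly the hip span (40 px)
  bout <- toy_bout(20, coords = list(
    left_ankle = function(f) cbind(100, 320),
    right_ankle = function(f) cbind(140, 320)
  ))
  traj <- threshold_and_impute(bout, 0)
  ctx <- normalization_context(traj)
  expect_equal(avg_step_width(traj, ctx), 1.0)

  coincident <- toy_bout(20, coords = list(
    left_ankle = function(f) cbind(120, 320),
    right_ankle = function(f) cbind(120, 320)
  ))
  traj2 <- threshold_and_impute(coincident, 0)
  expect_equal(avg_step_width(traj2, normalization_context(traj2)), 0)
})

test_that("per-step widths sample the strike frames and share the CV convention", {
  # width 16 px at frame 0 (ratio .4), 24 px at frame 10 (ratio .6)
  widths_px <- c(rep(16, 10), rep(24, 10))
  bout <- toy_bout(20, coords = list(
    left_ankle = function(f) cbind(120 - widths_px / 2, 320),
    right_ankle = function(f) cbind(120 + widths_px / 2, 320)
  ))
  traj <- threshold_and_impute(bout, 0)
  ctx <- normalization_context(traj)
  ev <- tibble::tibble(foot = c("left", "right"), frame = c(0, 10),
                       time_s = c(0, 10 / 30))
  w <- step_widths_per_step(traj, ev, ctx)
  expect_equal(w, c(0.4, 0.6))
  expect_equal(cv(w), 0.2828427, tolerance = 1e-6)
  # identical widths at all strikes give CV 0
  expect_equal(cv(c(0.5, 0.5, 0.5)), 0)
})

test_that("leg length averages per-foot normalized hip-ankle distances at strikes", {
  # hip span 1 px; left hip (0,0), left ankle (0,2.8); right hip (1,0),
  # right ankle (1,3.2) -> per-foot means 2.8 and 3.2 -> 3.0
  bout <- toy_bout(10, coords = list(
    left_hip = function(f) cbind(0, 0),
    right_hip = function(f) cbind(1, 0),
    left_ankle = function(f) cbind(0, 2.8),
    right_ankle = function(f) cbind(1, 3.2)
  ))
  traj <- threshold_and_impute(bout, 0)
  ctx <- normalization_context(traj, floor_px = 0.5)
  ev <- tibble::tibble(foot = c("left", "right"), frame = c(2, 5),
                       time_s = c(2, 5) / 30)
  expect_equal(leg_length_estimate(traj, ev, ctx), 3.0)
  # a foot without strikes falls back to the other foot's mean
  expect_message(
    ll <- leg_length_estimate(traj, ev[ev$foot == "left", ], ctx),
    "other foot")
  expect_equal(ll, 2.8)
})

test_that("the eXCOM offset is v / sqrt(g / leg length)", {
  com <- tibble::tibble(frame = 0:9, time_s = (0:9) / 30,
                        ecom_x = 100, ecom_y = 50, span = 40,
                        v_norm = 0)
  out <- excom_series(com, leg_length = 1)
  expect_equal(out$excom_x_norm, out$ecom_x / out$span) # zero velocity
  com$v_norm <- 0.1
  out2 <- excom_series(com, leg_length = 1, g = 9.81)
  expect_equal(unique(out2$excom_dx), 0.1 / sqrt(9.81))
  expect_equal(unique(out2$excom_dx), 0.03193, tolerance = 1e-4)
})

test_that("eMOS is zero when the eXCOM coincides with the stance ankle", {
  # static pose, ankle exactly at the eCOM, zero velocity
  bout <- toy_bout(30, coords = list(
    left_ankle = function(f) cbind(120, 320),
    right_ankle = function(f) cbind(120, 320)
  ))
  traj <- threshold_and_impute(bout, 0)
  ctx <- normalization_context(traj)
  ev <- tibble::tibble(foot = c("left", "right", "left"),
                       frame = c(0, 10, 20), time_s = c(0, 10, 20) / 30)
  mos <- emos(traj, ev, ctx)
  expect_equal(mos$avg_emos, 0)
  expect_equal(mos$min_emos, 0)
})

test_that("a constant lateral margin is reported as avg = min", {
  # stance ankle 12 px (0.3 span) lateral of the eCOM in every frame
  bout <- toy_bout(30, coords = list(
    left_ankle = function(f) cbind(120 - 12, 320),
    right_ankle = function(f) cbind(120 + 12, 320)
  ))
  traj <- threshold_and_impute(bout, 0)
  ctx <- normalization_context(traj)
  ev <- tibble::tibble(foot = c("right", "right", "right"),
                       frame = c(0, 10, 20), time_s = c(0, 10, 20) / 30)
  mos <- emos(traj, ev, ctx)
  expect_equal(mos$avg_emos, 0.3)
  expect_equal(mos$min_emos, 0.3)
})

test_that("eMOS statistics equal a brute-force per-frame/per-step computation", {
  sim <- simulate_bout(gait_sim_params(seed = 13))
  traj <- filter_trajectory(threshold_and_impute(sim$bout, 0.4))
  ctx <- normalization_context(traj)
  ev <- foot_strikes(traj)
  mos <- emos(traj, ev, ctx)

  # independent naive computation from the same trajectory
  ll <- leg_length_estimate(traj, ev, ctx)
  wide <- tidyr::pivot_wider(
    traj[traj$keypoint %in% c("left_hip", "right_hip", "left_ankle",
                              "right_ankle"), ],
    id_cols = c("frame", "time_s"), names_from = "keypoint",
    values_from = c("x", "y"))
  wide <- wide[order(wide$frame), ]
  ecx <- (wide$x_left_hip + wide$x_right_hip) / 2
  span <- sqrt((wide$x_left_hip - wide$x_right_hip)^2 +
                 (wide$y_left_hip - wide$y_right_hip)^2)
  n <- nrow(wide)
  v <- numeric(n)
  for (i in 2:(n - 1)) v[i] <- (ecx[i + 1] - ecx[i - 1]) / 2 * 30
  v[1] <- (ecx[2] - ecx[1]) * 30
  v[n] <- (ecx[n] - ecx[n - 1]) * 30
  vn <- v / span
  ev_sorted <- ev[order(ev$time_s), ]
  m <- rep(NA_real_, n)
  for (i in 1:n) {
    t <- wide$time_s[i]
    k <- max(which(ev_sorted$time_s <= t), 1)
    if (length(which(ev_sorted$time_s <= t)) == 0) k <- 1
    foot <- ev_sorted$foot[k]
    ax <- if (foot == "left") wide$x_left_ankle[i] else wide$x_right_ankle[i]
    s <- if (ax >= ecx[i]) 1 else -1
    m[i] <- s * ((ax - ecx[i]) / span[i] - vn[i] / sqrt(9.81 / ll))
  }
  use <- wide$time_s >= min(ev_sorted$time_s)
  expect_equal(mos$avg_emos, mean(m[use]), tolerance = 1e-6)
  mins <- c()
  for (k in 1:(nrow(ev_sorted) - 1)) {
    in_step <- wide$time_s >= ev_sorted$time_s[k] &
      wide$time_s < ev_sorted$time_s[k + 1]
    mins <- c(mins, min(m[in_step]))
  }
  expect_equal(mos$min_emos, mean(mins), tolerance = 1e-6)
})

test_that("per-step minima average below the per-frame average", {
  for (s in c(3, 8, 15)) {
    sim <- simulate_bout(gait_sim_params(seed = s))
    fv <- extract_features(sim$bout)
    expect_lte(fv$min_emos, fv$avg_emos)
  }
})

test_that("feature extraction is deterministic and rejects too-short bouts", {
  sim <- simulate_bout(gait_sim_params(seed = 17))
  f1 <- extract_features(sim$bout)
  f2 <- extract_features(sim$bout)
  expect_identical(f1, f2)
  expect_false(any(is.na(f1[, gait_feature_names()])))

  short <- simulate_bout(gait_sim_params(seed = 17, duration_s = 2,
                                         cadence = 60))
  err <- tryCatch(extract_features(short$bout),
                  gaitvision_bout_rejected = function(e) e)
  expect_s3_class(err, "gaitvision_bout_rejected")
  expect_identical(err$reason, "too_few_steps")
})

test_that("all seven features are invariant to pixel scaling and translation", {
  sim <- simulate_bout(gait_sim_params(seed = 23, pixel_noise_sd = 0,
                                       dropout_rate = 0))
  base <- extract_features(sim$bout)
  scaled <- sim$bout
  scaled$x <- scaled$x * 2.5
  scaled$y <- scaled$y * 2.5
  shifted <- sim$bout
  shifted$x <- shifted$x + 310
  shifted$y <- shifted$y - 45
  for (variant in list(scaled, shifted)) {
    fv <- extract_features(variant)
    for (f in gait_feature_names()) {
      expect_equal(fv[[f]], base[[f]], tolerance = 1e-6,
                   info = f)
    }
  }
})

test_that("baselines average retained in-window bouts", {
  fv <- function(id, date, cad) {
    tibble::tibble(
      bout_id = paste0(id, date), participant_id = id, recorded_at = date,
      cadence = cad, si_step_time = 0.1, cv_step_time = 0.1,
      avg_step_width = 0.5, cv_step_width = 0.1, avg_emos = 0.2,
      min_emos = 0.1, n_steps = 10L, duration_s = 10
    )
  }
  enr <- tibble::tibble(participant_id = "P01",
                        enrollment_date = "2020-01-01")
  single <- baseline_aggregate(fv("P01", "2020-01-05", 100), enr)
  expect_equal(single$cadence, 100)
  expect_identical(single$n_bouts, 1L)

  # a bout on day 20 is outside the 14-day window
  two <- dplyr::bind_rows(fv("P01", "2020-01-05", 100),
                          fv("P01", "2020-01-21", 80))
  agg <- baseline_aggregate(two, enr)
  expect_equal(agg$cadence, 100)
  expect_identical(agg$n_bouts, 1L)

  set.seed(1)
  cads <- runif(10, 80, 120)
  many <- dplyr::bind_rows(lapply(seq_along(cads), function(i) {
    fv("P01", sprintf("2020-01-%02d", i + 1), cads[i])
  }))
  agg10 <- baseline_aggregate(many, enr)
  expect_equal(agg10$cadence, mean(cads), tolerance = 1e-9)
  expect_identical(agg10$n_bouts, 10L)

  # participants with no in-window bouts are dropped with a message
  expect_message(
    none <- baseline_aggregate(fv("P02", "2020-03-01", 90),
                               tibble::tibble(participant_id = "P02",
                                              enrollment_date = "2020-01-01")),
    "window")
  expect_identical(nrow(none), 0L)
})
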