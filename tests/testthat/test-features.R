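test_that("summary statistics match hand values and the brute-force oracle", {
  s <- summary_stats(rep(5, 6))
  expect_equal(unlist(s[c("max", "min", "median", "range", "rms", "cv")]),
               c(max = 5, min = 5, median = 5, range = 0, rms = 5, cv = 0))

  s <- summary_stats(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$range, 2)
  expect_equal(s$cv, 0.5)  # sample SD 1, mean 2

  # RMS of a full-period sine tends to A / sqrt(2)
  A <- 3.7
  x <- A * sin(2 * pi * seq(0, 1, length.out = 10001)[-1])
  expect_equal(summary_stats(x)$rms, A / sqrt(2), tolerance = 1e-3)

  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(2:40, 1), sd = sample(c(0.01, 1, 100), 1))
    expect_equal(summary_stats(x), bf_summary_stats(x))
  }

  expect_error(summary_stats(1), class = "tug_feature_error")
  expect_warning(s0 <- summary_stats(c(-1, 1)), "zero")
  expect_true(is.na(s0$cv))
})

test_that("jerk is the successive absolute difference, in acceleration units", {
  j <- jerk_stats(c(0, 1, 3))
  expect_equal(j$max_jerk, 2)
  expect_equal(j$mean_jerk, 1.5)
  expect_equal(jerk_stats(rep(2.2, 9)), list(max_jerk = 0, mean_jerk = 0))

  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(2:30, 1))
    expect_equal(jerk_stats(x), bf_jerk(x))
  }

  # optional true time-derivative variant
  expect_equal(jerk_stats(c(0, 1, 3), per_second = TRUE, dt = 0.2)$max_jerk, 10)
  expect_error(jerk_stats(3), class = "tug_feature_error")
  expect_error(jerk_stats(c(0, 1), per_second = TRUE), class = "tug_feature_error")
})

test_that("temporal features: durations, PODs and the partition identity", {
  iv <- subtask_intervals(c(0, 3), c(3, 6), c(6, 9), c(9, 12), c(12, 15))
  tf <- temporal_features(iv)
  expect_equal(tf[["temporal_duration_walk"]], 6)
  expect_equal(tf[["temporal_pod_walk"]], 40)  # 6 s of a 15 s TUG
  expect_equal(sum(tf[paste0("temporal_pod_",
                             c("sit_to_stand", "walk", "turn", "turn_to_sit"))]),
               100)
  expect_equal(tf[["temporal_tug_duration"]], 15)

  tr <- fixture_trial(2)
  tf2 <- temporal_features(truth_intervals(tr$truth))
  b <- tr$truth$boundaries
  expect_equal(tf2[["temporal_duration_sit_to_stand"]], diff(b$sit_to_stand))
  expect_equal(tf2[["temporal_duration_walk"]],
               diff(b$walk_forward) + diff(b$walk_back))
  expect_equal(tf2[["temporal_duration_turn"]], diff(b$turn))
})

test_that("legs and knee angles follow the joint-vector definitions", {
  f <- matrix(0, 25, 3)
  f[14, ] <- c(-0.1, -0.5, 0)   # joint 13, left knee
  f[18, ] <- c(0.1, -0.5, 0)    # joint 17, right knee
  expect_equal(legs_angle(f), 2 * atan(0.1 / 0.5) * 180 / pi, tolerance = 1e-10)

  # right knee: vertex joint 17, vectors to joints 16 (hip) and 18 (ankle)
  f2 <- matrix(0, 25, 3)
  f2[17, ] <- c(0, 1, 0)    # joint 16 hip
  f2[18, ] <- c(0, 0, 0)    # joint 17 knee (vertex)
  f2[19, ] <- c(0, -1, 0)   # joint 18 ankle: collinear, opposite -> straight
  expect_equal(knee_angle(f2, "right"), 180)
  f2[19, ] <- c(1, 0, 0)    # orthogonal -> 90 degrees
  expect_equal(knee_angle(f2, "right"), 90)

  # left knee mirrored through joints 12, 13, 14
  f3 <- matrix(0, 25, 3)
  f3[13, ] <- c(0, 1, 0)
  f3[15, ] <- c(1, 0, 0)
  expect_equal(knee_angle(f3, "left"), 90)

  f4 <- matrix(0, 25, 3)
  expect_warning(a <- legs_angle(f4), "zero-length")
  expect_true(is.na(a))
})

test_that("the simulator realizes the knee angles it samples", {
  tr <- fixture_trial(3)
  iv <- truth_intervals(tr$truth)
  fv <- extract_features(tr$imu, tr$skeleton, iv)
  expect_equal(fv[["keypoint_right_knee_angle_walk"]],
               tr$truth$subject_params$knee_angle_walk, tolerance = 0.01)
  expect_equal(fv[["keypoint_right_knee_angle_turn"]],
               tr$truth$subject_params$knee_angle_turn, tolerance = 0.01)
})

test_that("step metrics follow their definitions on a constructed gait", {
  # 30 Hz skeleton, two walk segments, 8 steps each of 0.4 s
  rate <- 30
  t <- seq(0, 12, by = 1 / rate)
  iv <- list(c(2, 5.2), c(6.8, 10))
  sep <- numeric(length(t))
  for (seg in iv) {
    sel <- t >= seg[1] & t < seg[2]
    sep[sel] <- 0.35 * sin(pi * (t[sel] - seg[1]) / 0.4)
  }
  joints <- matrix(0, length(t), 75)
  joints[, tugfall:::joint_col(14, "z")] <- sep / 2
  joints[, tugfall:::joint_col(18, "z")] <- -sep / 2
  joints[, tugfall:::joint_col(14, "x")] <- -0.07
  joints[, tugfall:::joint_col(18, "x")] <- 0.07
  joints[, 2] <- seq_along(t) * 1e-6  # keep columns finite/nonconstant
  sk <- skeleton_recording(t, joints, rate)
  sm <- step_metrics(sk, iv)
  expect_equal(sm$step_counts, 16)
  expect_equal(sm$step_length, 6 / 16)       # 0.375 m by definition
  expect_equal(sm$step_duration, 6.4 / 16)   # 0.4 s
  expect_equal(sm$step_width, 0.14)

  # no oscillation -> no gait detected
  joints0 <- joints
  joints0[, tugfall:::joint_col(14, "z")] <- 0
  joints0[, tugfall:::joint_col(18, "z")] <- 0
  sk0 <- skeleton_recording(t, joints0, rate)
  expect_error(step_metrics(sk0, iv), "no gait", class = "tug_feature_error")
})

test_that("feature schema is bijective with the published counts", {
  nms <- feature_names()
  expect_length(nms, 142)
  expect_false(anyDuplicated(nms) > 0)
  # per-axis counts: 22 acceleration, 18 angular velocity
  for (ax in c("V", "ML", "AP")) {
    expect_length(grep(paste0("^acc_[a-z_]+_", ax, "_"), nms), 22)
  }
  for (ax in c("yaw", "pitch", "roll")) {
    expect_length(grep(paste0("^gyr_[a-z_]+_", ax, "_"), nms), 18)
  }
  expect_length(grep("^temporal_", nms), 9)
  expect_length(grep("^keypoint_", nms), 10)
})

test_that("extract_features yields a complete, unit-consistent 142-vector", {
  tr <- fixture_trial(1)
  iv <- segment_subtasks(tr$imu)
  fv <- extract_features(tr$imu, tr$skeleton, iv,
                         meta = data.frame(age = 80, gender = "F",
                                           assistance = "yes"))
  expect_length(fv, 142)
  expect_identical(names(fv), feature_names())
  expect_false(any(is.na(fv)))
  expect_false(attr(fv, "incomplete"))
  expect_equal(fv[["gender"]], 0)
  expect_equal(fv[["assistance"]], 1)
  expect_equal(fv[["age"]], 80)
  # angles in [0, 180], PODs in [0, 100]
  ang <- fv[grep("angle", names(fv))]
  expect_true(all(ang >= 0 & ang <= 180))
  pods <- fv[grep("^temporal_pod_", names(fv))]
  expect_true(all(pods >= 0 & pods <= 100))
  expect_equal(sum(pods), 100)
})

test_that("walk-phase statistics equal pooled-segment statistics", {
  tr <- fixture_trial(2)
  iv <- segment_subtasks(tr$imu)
  fv <- extract_features(tr$imu, tr$skeleton, iv)
  pooled <- tr$imu$acc$V[tr$imu$t >= iv$walk_forward[1] & tr$imu$t < iv$walk_forward[2] |
                           tr$imu$t >= iv$walk_back[1] & tr$imu$t < iv$walk_back[2]]
  ss <- summary_stats(pooled)
  expect_equal(fv[["acc_rms_V_walk"]], ss$rms)
  expect_equal(fv[["acc_median_V_walk"]], ss$median)
  expect_equal(fv[["acc_cv_V_walk"]], ss$cv)
  expect_equal(fv[["acc_range_V_walk"]], ss$range)
})

test_that("a starved subtask yields NA features and an incomplete flag", {
  tr <- fixture_trial(1)
  iv <- subtask_intervals(
    c(tr$truth$tug_start, tr$truth$tug_start + 0.05),  # < 2 samples at 5 Hz
    c(tr$truth$tug_start + 0.05, tr$truth$boundaries$turn[1]),
    tr$truth$boundaries$turn, tr$truth$boundaries$walk_back,
    tr$truth$boundaries$turn_to_sit
  )
  expect_warning(fv <- extract_features(tr$imu, tr$skeleton, iv), "incomplete")
  expect_true(attr(fv, "incomplete"))
  expect_true(any(is.na(fv[grep("sit_to_stand", names(fv))])))
})
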