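test_that("default profiles carry the published two-cohort contrasts", {
  p <- default_profiles()
  expect_equal(p$low$step_length_mean_sd, c(0.37, 0.07))
  expect_equal(p$high$step_length_mean_sd, c(0.31, 0.06))
  expect_equal(p$low$turn_to_sit_max_yaw_mean_sd[1], 161.28)
  expect_equal(p$high$turn_to_sit_max_yaw_mean_sd[1], 122.25)
  expect_lt(p$low$step_width_mean_sd[1], p$high$step_width_mean_sd[1])
  expect_equal(p$low$step_width_mean_sd[1], 0.13)
  expect_equal(p$high$step_width_mean_sd[1], 0.16)
  # turn pitch drift flips sign between the cohorts
  expect_gt(p$low$pelvic_pitch_offset_turn, 0)
  expect_lt(p$high$pelvic_pitch_offset_turn, 0)
})

test_that("profile validation rejects broken inputs", {
  p <- default_profiles()$low
  p$step_length_mean_sd <- c(-0.3, 0.07)
  expect_error(simulate_trial(p, seed = 1), class = "tug_profile_error")
  p <- default_profiles()$low
  p$gyro_noise_sd <- NaN
  expect_error(simulate_trial(p, seed = 1), class = "tug_profile_error")
  expect_error(gait_profile(
    step_length_mean_sd = c(0.37, -1), step_width_mean_sd = c(0.13, 0.03),
    step_duration_mean_sd = c(0.33, 0.03), turn_max_yaw_mean_sd = c(165, 40),
    turn_to_sit_max_yaw_mean_sd = c(161, 44),
    knee_angle_walk_mean_sd = c(159, 5), knee_angle_turn_mean_sd = c(158, 10),
    pelvic_pitch_offset_turn = 2
  ), class = "tug_profile_error")
})

test_that("simulate_trial is bit-identical under a fixed seed", {
  a <- simulate_trial(default_profiles()$low, seed = 11)
  b <- simulate_trial(default_profiles()$low, seed = 11)
  expect_identical(a$imu, b$imu)
  expect_identical(a$skeleton, b$skeleton)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_trial(default_profiles()$low, seed = 12)
  expect_false(identical(a$imu$gyr$yaw, c_$imu$gyr$yaw))
})

test_that("seated baselines are quiet: |yaw| < 3 gyro_noise_sd at every sample", {
  p <- default_profiles()$low
  for (seed in 1:5) {
    tr <- simulate_trial(p, seed = seed)
    sit <- tr$imu$t < tr$truth$tug_start | tr$imu$t > tr$truth$tug_end
    expect_true(all(abs(tr$imu$gyr$yaw[sit]) < 3 * p$gyro_noise_sd))
  }
})

test_that("ground-truth intervals tile the active portion without gaps", {
  for (seed in c(2, 3)) {
    for (group in c("low", "high")) {
      truth <- fixture_trial(seed, group)$truth
      b <- truth$boundaries
      ord <- c("sit_to_stand", "walk_forward", "turn", "walk_back", "turn_to_sit")
      for (i in 1:4) expect_equal(b[[ord[i]]][2], b[[ord[i + 1]]][1])
      expect_equal(b$sit_to_stand[1], truth$tug_start)
      expect_equal(b$turn_to_sit[2], truth$tug_end)
      expect_true(all(vapply(b, diff, numeric(1)) > 0))
      expect_equal(truth$true_step_count,
                   length(unlist(truth$step_events, use.names = FALSE)))
    }
  }
})

test_that("realized step length matches the profile mean over 100 trials", {
  p <- default_profiles()$low
  L <- vapply(1:100, function(s) {
    6 / simulate_trial(p, seed = 4000 + s)$truth$true_step_count
  }, numeric(1))
  se <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - 0.37), 2 * se)
})

test_that("sample_cohort assembles labeled subjects with valid BBS scores", {
  coh <- sample_cohort(4, 3, seed = 21)
  expect_length(coh, 7)
  labs <- vapply(coh, function(r) r$meta$label, character(1))
  expect_equal(sum(labs == "low"), 4)
  expect_equal(sum(labs == "high"), 3)
  for (r in coh) {
    expect_true(r$meta$bbs >= 0 && r$meta$bbs <= 56)
    expect_identical(r$meta$label, if (r$meta$bbs > 50) "low" else "high")
    expect_gte(r$meta$age, 65)
  }
  # minimal cohort keeps both labels
  mini <- sample_cohort(1, 1, seed = 3)
  expect_setequal(vapply(mini, function(r) r$meta$label, character(1)),
                  c("low", "high"))
  expect_error(sample_cohort(0, 5, seed = 1), class = "tug_validation_error")
})

test_that("sample_cohort is deterministic in its master seed", {
  a <- sample_cohort(2, 2, seed = 31)
  b <- sample_cohort(2, 2, seed = 31)
  expect_identical(lapply(a, `[[`, "meta"), lapply(b, `[[`, "meta"))
  expect_identical(a[[1]]$imu, b[[1]]$imu)
  expect_identical(a[[4]]$skeleton, b[[4]]$skeleton)
})

test_that("pooled cohort age matches the demographic mixture mean", {
  # mixture mean (26 x 77.38 + 15 x 82.00) / 41 = 79.07
  ages <- unlist(lapply(1:5, function(s) {
    vapply(sample_cohort(26, 15, seed = 500 + s), function(r) r$meta$age,
           numeric(1))
  }))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 79.07), 2 * se)
})

test_that("median turn pitch is sign-consistent with the profile", {
  p <- default_profiles()
  signs <- vapply(1:20, function(s) {
    med <- function(tr) {
      sel <- tr$imu$t >= tr$truth$boundaries$turn[1] &
        tr$imu$t < tr$truth$boundaries$turn[2]
      median(tr$imu$gyr$pitch[sel])
    }
    c(med(simulate_trial(p$low, seed = 6000 + s)) > 0,
      med(simulate_trial(p$high, seed = 7000 + s)) < 0)
  }, logical(2))
  expect_gte(mean(signs[1, ]), 0.9)
  expect_gte(mean(signs[2, ]), 0.9)
})
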