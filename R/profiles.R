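#' Gait profile for the TUG simulator
#'
#' A `tug_profile` bundles the cohort-level distributions the synthetic-data
#' generator draws each subject's gait from. Means and SDs are given as
#' `c(mean, sd)` pairs; scalar fields apply to every subject of the profile.
#'
#' @param step_length_mean_sd step length `c(mean, sd)` in meters.
#' @param step_width_mean_sd mean lateral inter-ankle distance `c(mean, sd)`
#'   in meters.
#' @param step_duration_mean_sd duration of one step `c(mean, sd)` in
#'   seconds (walking speed is the derived ratio step length / step
#'   duration).
#' @param turn_max_yaw_mean_sd peak yaw angular velocity of the mid-test
#'   180-degree turn, `c(mean, sd)` in deg/s.
#' @param turn_to_sit_max_yaw_mean_sd peak yaw angular velocity of the final
#'   turn-to-sit, `c(mean, sd)` in deg/s.
#' @param knee_angle_walk_mean_sd mean knee angle during walking
#'   `c(mean, sd)` in degrees (180 = fully extended).
#' @param knee_angle_turn_mean_sd mean knee angle during the turn
#'   `c(mean, sd)` in degrees.
#' @param pelvic_pitch_offset_turn median pitch angular velocity held during
#'   the turn, deg/s; its sign encodes anterior (negative) vs posterior
#'   pelvic drift while turning.
#' @param walk_pitch_rms_mean_sd target RMS of the pitch gait oscillation
#'   while walking, `c(mean, sd)` in deg/s.
#' @param sit_to_stand_duration sit-to-stand duration `c(mean, sd)` seconds.
#' @param turn_duration turn duration `c(mean, sd)` seconds.
#' @param turn_to_sit_duration turn-to-sit duration `c(mean, sd)` seconds.
#' @param acc_v_peak_tts peak vertical-acceleration excursion above the
#'   upright baseline (1.0 sensor units) during turn-to-sit, `c(mean, sd)`.
#' @param roll_peak_tts peak roll angular velocity during turn-to-sit,
#'   `c(mean, sd)` in deg/s.
#' @param accel_noise_sd white accelerometer noise SD, sensor units.
#' @param gyro_noise_sd white gyroscope noise SD, deg/s.
#' @param age_mean_sd cohort age distribution `c(mean, sd)`, years
#'   (truncated at 65 when sampling).
#' @param assistance_prob probability a subject uses walking assistance in
#'   daily life.
#' @param prop_male probability a subject is male.
#'
#' @return an object of class `tug_profile` (a validated list).
#' @seealso [default_profiles()] for the published two-cohort defaults.
#' @export
gait_profile <- function(step_length_mean_sd,
                         step_width_mean_sd,
                         step_duration_mean_sd,
                         turn_max_yaw_mean_sd,
                         turn_to_sit_max_yaw_mean_sd,
                         knee_angle_walk_mean_sd,
                         knee_angle_turn_mean_sd,
                         pelvic_pitch_offset_turn,
                         walk_pitch_rms_mean_sd = c(8.0, 2.0),
                         sit_to_stand_duration = c(2.0, 0.3),
                         turn_duration = c(2.2, 0.3),
                         turn_to_sit_duration = c(3.2, 0.4),
                         acc_v_peak_tts = c(0.14, 0.05),
                         roll_peak_tts = c(15, 8),
                         accel_noise_sd = 0.01,
                         gyro_noise_sd = 2.0,
                         age_mean_sd = c(78, 6),
                         assistance_prob = 0.2,
                         prop_male = 0.12) {
  p <- list(
    step_length_mean_sd = as.numeric(step_length_mean_sd),
    step_width_mean_sd = as.numeric(step_width_mean_sd),
    step_duration_mean_sd = as.numeric(step_duration_mean_sd),
    turn_max_yaw_mean_sd = as.numeric(turn_max_yaw_mean_sd),
    turn_to_sit_max_yaw_mean_sd = as.numeric(turn_to_sit_max_yaw_mean_sd),
    knee_angle_walk_mean_sd = as.numeric(knee_angle_walk_mean_sd),
    knee_angle_turn_mean_sd = as.numeric(knee_angle_turn_mean_sd),
    pelvic_pitch_offset_turn = as.numeric(pelvic_pitch_offset_turn),
    walk_pitch_rms_mean_sd = as.numeric(walk_pitch_rms_mean_sd),
    sit_to_stand_duration = as.numeric(sit_to_stand_duration),
    turn_duration = as.numeric(turn_duration),
    turn_to_sit_duration = as.numeric(turn_to_sit_duration),
    acc_v_peak_tts = as.numeric(acc_v_peak_tts),
    roll_peak_tts = as.numeric(roll_peak_tts),
    accel_noise_sd = as.numeric(accel_noise_sd),
    gyro_noise_sd = as.numeric(gyro_noise_sd),
    age_mean_sd = as.numeric(age_mean_sd),
    assistance_prob = as.numeric(assistance_prob),
    prop_male = as.numeric(prop_male)
  )
  validate_profile(p)
  structure(p, class = "tug_profile")
}

validate_profile <- function(p) {
  pairs <- c(
    "step_length_mean_sd", "step_width_mean_sd", "step_duration_mean_sd",
    "turn_max_yaw_mean_sd", "turn_to_sit_max_yaw_mean_sd",
    "knee_angle_walk_mean_sd", "knee_angle_turn_mean_sd",
    "walk_pitch_rms_mean_sd", "sit_to_stand_duration", "turn_duration",
    "turn_to_sit_duration", "acc_v_peak_tts", "roll_peak_tts", "age_mean_sd"
  )
  for (f in pairs) {
    v <- p[[f]]
    if (length(v) != 2L || !all(is.finite(v))) {
      tug_stop("tug_profile_error", "profile field '%s' must be finite c(mean, sd)", f)
    }
    if (v[2] < 0) tug_stop("tug_profile_error", "profile field '%s' has SD < 0", f)
  }
  for (f in c("pelvic_pitch_offset_turn", "accel_noise_sd", "gyro_noise_sd",
              "assistance_prob", "prop_male")) {
    if (length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      tug_stop("tug_profile_error", "profile field '%s' must be a finite scalar", f)
    }
  }
  if (p$step_length_mean_sd[1] <= 0) {
    tug_stop("tug_profile_error", "step length must be positive")
  }
  if (p$turn_max_yaw_mean_sd[1] <= 0 || p$turn_to_sit_max_yaw_mean_sd[1] <= 0) {
    tug_stop("tug_profile_error", "turn yaw peak magnitudes must be positive")
  }
  for (f in c("knee_angle_walk_mean_sd", "knee_angle_turn_mean_sd")) {
    if (p[[f]][1] <= 90 || p[[f]][1] >= 180) {
      tug_stop("tug_profile_error", "knee angle mean must lie in (90, 180) degrees")
    }
  }
  if (p$accel_noise_sd < 0 || p$gyro_noise_sd < 0) {
    tug_stop("tug_profile_error", "noise SDs must be >= 0")
  }
  invisible(p)
}

#' Published two-cohort gait profiles
#'
#' Returns the default low-fall-risk and high-fall-risk gait profiles. The
#' contrasts carried by the defaults are those reported for the two BBS-
#' defined cohorts: step length 0.37 vs 0.31 m, step width 0.13 vs 0.16 m,
#' turn-to-sit peak yaw 161.28 vs 122.25 deg/s, right knee angle while
#' walking 158.95 vs 162.18 degrees (high-risk subjects keep the knee more
#' extended), an opposite-signed median pitch angular velocity during the
#' turn (+2.10 vs -2.80 deg/s, anterior pelvic drift in the high-risk
#' group), and demographics (age 77.38 +/- 5.34 vs 82.00 +/- 7.36 years,
#' walking-assistance use 4/26 vs 10/15).
#'
#' @return a list with elements `low` and `high`, both [gait_profile()]s.
#' @examples
#' p <- default_profiles()
#' p$low$step_length_mean_sd   # 0.37 0.07
#' p$high$turn_to_sit_max_yaw_mean_sd
#' @export
default_profiles <- function() {
  low <- gait_profile(
    step_length_mean_sd = c(0.37, 0.07),
    step_width_mean_sd = c(0.13, 0.03),
    step_duration_mean_sd = c(0.33, 0.03),
    turn_max_yaw_mean_sd = c(165, 40),
    turn_to_sit_max_yaw_mean_sd = c(161.28, 44.40),
    knee_angle_walk_mean_sd = c(158.95, 5.48),
    knee_angle_turn_mean_sd = c(157.71, 10.60),
    pelvic_pitch_offset_turn = 2.10,
    walk_pitch_rms_mean_sd = c(8.16, 2.41),
    sit_to_stand_duration = c(2.0, 0.3),
    turn_duration = c(2.2, 0.3),
    turn_to_sit_duration = c(3.2, 0.4),
    acc_v_peak_tts = c(0.14, 0.05),
    roll_peak_tts = c(18.72, 11.32),
    age_mean_sd = c(77.38, 5.34),
    assistance_prob = 4 / 26,
    prop_male = 2 / 26
  )
  high <- gait_profile(
    step_length_mean_sd = c(0.31, 0.06),
    step_width_mean_sd = c(0.16, 0.03),
    step_duration_mean_sd = c(0.40, 0.04),
    turn_max_yaw_mean_sd = c(140, 35),
    turn_to_sit_max_yaw_mean_sd = c(122.25, 33.24),
    knee_angle_walk_mean_sd = c(162.18, 3.19),
    knee_angle_turn_mean_sd = c(164.44, 9.05),
    pelvic_pitch_offset_turn = -2.80,
    walk_pitch_rms_mean_sd = c(6.64, 1.77),
    sit_to_stand_duration = c(2.4, 0.35),
    turn_duration = c(2.6, 0.35),
    turn_to_sit_duration = c(3.6, 0.45),
    acc_v_peak_tts = c(0.19, 0.07),
    roll_peak_tts = c(6.67, 11.55),
    age_mean_sd = c(82.00, 7.36),
    assistance_prob = 10 / 15,
    prop_male = 3 / 15
  )
  list(low = low, high = high)
}

#' @export
print.tug_profile <- function(x, ...) {
  cat("<tug_profile>\n")
  cat(sprintf("  step length  %.3f +/- %.3f m\n",
              x$step_length_mean_sd[1], x$step_length_mean_sd[2]))
  cat(sprintf("  step width   %.3f +/- %.3f m\n",
              x$step_width_mean_sd[1], x$step_width_mean_sd[2]))
  cat(sprintf("  turn-to-sit peak yaw %.2f +/- %.2f deg/s\n",
              x$turn_to_sit_max_yaw_mean_sd[1], x$turn_to_sit_max_yaw_mean_sd[2]))
  cat(sprintf("  turn pitch offset %+.2f deg/s\n", x$pelvic_pitch_offset_turn))
  invisible(x)
}
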