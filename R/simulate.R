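# Synthetic TUG trial generator.
#
# A trial is a phase-templated composition on one clock:
#   sit (quiet) | sit-to-stand | walk forward | turn | walk back |
#   turn-to-sit | sit (quiet)
# Gyroscope and accelerometer channels are piecewise-smooth parametric
# templates (raised-cosine-edged pulses for transfers and turns, sinusoidal
# gait-cycle oscillations while walking) plus truncated white Gaussian
# noise; the skeleton stream is a pelvis trajectory walking 3 m out and
# back with leg joints posed to realize the sampled step length, step
# width and knee angles exactly.

# Evaluate expr with a local RNG seeded at `seed`, restoring global state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Gaussian noise truncated at +/- 3 SD: quiescent baselines stay strictly
# inside the 3-sigma activity floor the segmenter's threshold relies on.
rnoise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  rnorm_trunc(n, 0, sd, lo = -2.99 * sd, hi = 2.99 * sd)
}

#' Simulate one instrumented TUG trial
#'
#' Draws a subject's gait realization from a [gait_profile()] and renders a
#' paired lumbar-IMU and depth-camera skeleton recording plus the ground
#' truth needed to validate segmentation and feature extraction. The
#' walking distance is exactly 3 m each way, so the 6 m step-length
#' denominator used downstream is exact.
#'
#' Signal anatomy (matching what the segmenter relies on): near-zero gyro
#' during the seated lead-in/out; a pitch burst during sit-to-stand; small
#' gait-cycle oscillations while walking; a yaw pulse reaching the sampled
#' peak during the 180-degree turn; combined yaw + pitch activity during
#' turn-to-sit; a constant signed pitch offset (anterior/posterior pelvic
#' drift) during the turn.
#'
#' @param profile a [gait_profile()].
#' @param seed integer; fixes all randomness of the trial.
#' @param rate IMU sampling rate in Hz (default 5, the modeled hardware).
#' @param skel_rate skeleton frame rate in Hz (default 30).
#' @param skel_noise_sd per-coordinate skeleton noise SD in meters.
#' @return a list with elements `imu` (`tug_imu`), `skeleton`
#'   (`tug_skeleton`) and `truth` (`tug_truth`: phase `boundaries`,
#'   `tug_start`/`tug_end`, `step_events`, `true_step_count`, and the
#'   realized per-subject draws in `subject_params`).
#' @examples
#' trial <- simulate_trial(default_profiles()$low, seed = 1)
#' trial$truth$true_step_count
#' @export
simulate_trial <- function(profile, seed, rate = 5, skel_rate = 30,
                           skel_noise_sd = 0.005) {
  if (!inherits(profile, "tug_profile")) {
    profile <- structure(profile, class = "tug_profile")
  }
  validate_profile(profile)
  stopifnot(rate > 0, skel_rate > 0)
  with_local_seed(seed, simulate_trial_impl(profile, rate, skel_rate, skel_noise_sd))
}

simulate_trial_impl <- function(p, rate, skel_rate, skel_noise_sd) {
  draw <- function(f, lo = -Inf, hi = Inf) rnorm_trunc(1, f[1], f[2], lo, hi)

  L <- draw(p$step_length_mean_sd, 0.15, 0.60)
  width <- draw(p$step_width_mean_sd, 0.05, 0.30)
  sdur <- draw(p$step_duration_mean_sd, 0.25, 0.70)
  yaw_turn <- draw(p$turn_max_yaw_mean_sd, 30, Inf)
  yaw_tts <- draw(p$turn_to_sit_max_yaw_mean_sd, 30, Inf)
  knee_walk <- draw(p$knee_angle_walk_mean_sd, 120, 178)
  knee_turn <- draw(p$knee_angle_turn_mean_sd, 120, 178)
  pitch_rms <- draw(p$walk_pitch_rms_mean_sd, 2, Inf)
  sts_dur <- draw(p$sit_to_stand_duration, 1.0, Inf)
  turn_dur <- draw(p$turn_duration, 1.2, Inf)
  tts_dur <- draw(p$turn_to_sit_duration, 1.5, Inf)
  acc_v_peak <- draw(p$acc_v_peak_tts, 0.02, Inf)
  roll_peak <- draw(p$roll_peak_tts, 1, Inf)
  sts_pitch_peak <- rnorm_trunc(1, 40, 5, 25, 60)
  tts_pitch_peak <- -rnorm_trunc(1, 35, 5, 22, 55)

  n_steps <- max(4L, as.integer(round(6 / L)))
  n_fwd <- as.integer(ceiling(n_steps / 2))
  n_back <- n_steps - n_fwd
  wf_dur <- n_fwd * sdur
  wb_dur <- n_back * sdur

  sit_pre <- 2.5 + runif(1, 0, 0.3)
  t0 <- sit_pre
  t1 <- t0 + sts_dur
  t2 <- t1 + wf_dur
  t3 <- t2 + turn_dur
  t4 <- t3 + wb_dur
  t5 <- t4 + tts_dur
  t_end <- t5 + 2.5 + runif(1, 0, 0.3)

  ## ---- IMU stream -------------------------------------------------------
  t <- seq(0, t_end, by = 1 / rate)
  n <- length(t)
  mask_f <- tukey_pulse(t, t1, t2, 1, ramp = 0.2, bump = 0)
  mask_b <- tukey_pulse(t, t3, t4, 1, ramp = 0.2, bump = 0)
  stride_f <- 2 * pi * (t - t1) / (2 * sdur)
  stride_b <- 2 * pi * (t - t3) / (2 * sdur)

  gyr_yaw <- tukey_pulse(t, t2, t3, yaw_turn) +
    tukey_pulse(t, t4, t5, yaw_tts) +
    rnoise(n, p$gyro_noise_sd)

  amp_pitch <- sqrt(2) * pitch_rms
  gyr_pitch <- tukey_pulse(t, t0, t1, sts_pitch_peak) +
    amp_pitch * (sin(stride_f) * mask_f + sin(stride_b) * mask_b) +
    # pelvic drift starts as the turn begins: ramps sit outside [t2, t3] so
    # the median over the turn sees the full offset
    p$pelvic_pitch_offset_turn * tukey_pulse(t, t2 - 0.25, t3 + 0.25, 1, ramp = 0.25, bump = 0) +
    tukey_pulse(t, t4 + 0.45 * tts_dur, t5, tts_pitch_peak, ramp = 0.35) +
    rnoise(n, p$gyro_noise_sd)

  gyr_roll <- 4 * (cos(stride_f) * mask_f + cos(stride_b) * mask_b) +
    tukey_pulse(t, t4, t5, roll_peak) +
    rnoise(n, p$gyro_noise_sd)

  step_f <- 2 * pi * (t - t1) / sdur
  step_b <- 2 * pi * (t - t3) / sdur
  acc_V <- 1.0 + tukey_pulse(t, t0, t1, 0.12) +
    0.03 * (sin(step_f) * mask_f + sin(step_b) * mask_b) +
    tukey_pulse(t, t4, t5, acc_v_peak) +
    rnoise(n, p$accel_noise_sd)
  acc_ML <- tukey_pulse(t, t0, t1, 0.06) +
    0.025 * (sin(stride_f) * mask_f + sin(stride_b) * mask_b) +
    tukey_pulse(t, t4, t5, 0.07) +
    rnoise(n, p$accel_noise_sd)
  acc_AP <- tukey_pulse(t, t0, t1, 0.15) +
    0.03 * (sin(step_f + 1) * mask_f + sin(step_b + 1) * mask_b) +
    tukey_pulse(t, t4, t5, 0.13) +
    rnoise(n, p$accel_noise_sd)

  imu <- imu_recording(
    t = t,
    acc = data.frame(V = acc_V, ML = acc_ML, AP = acc_AP),
    gyr = data.frame(yaw = gyr_yaw, pitch = gyr_pitch, roll = gyr_roll),
    rate = rate
  )

  ## ---- Skeleton stream --------------------------------------------------
  ts <- seq(0, t_end, by = 1 / skel_rate)
  ns <- length(ts)

  # pelvis trajectory: x lateral, y vertical, z along the 3 m walkway
  pz <- numeric(ns)
  in_f <- ts >= t1 & ts < t2
  in_b <- ts >= t3 & ts < t4
  in_turn <- ts >= t2 & ts < t3
  pz[in_f] <- 3 * (ts[in_f] - t1) / wf_dur
  pz[in_turn] <- 3
  pz[in_b] <- 3 * (1 - (ts[in_b] - t3) / wb_dur)
  py <- 0.55 + 0.40 * smoothstep(ts, t0, t0 + 0.8 * sts_dur) -
    0.40 * smoothstep(ts, t4 + 0.5 * tts_dur, t5 - 0.05)
  px <- 0.02 * sin(2 * pi * (ts - t1) / (2 * sdur)) * (in_f | in_b)

  # continuous step phase: k steps completed so far
  k <- numeric(ns)
  k[in_f] <- (ts[in_f] - t1) / sdur
  k[in_turn] <- n_fwd
  k[in_b] <- n_fwd + (ts[in_b] - t3) / sdur
  k[ts >= t4] <- n_steps
  sep <- L * sin(pi * k)                      # signed AP ankle separation
  c_off <- 0.05 + (0.95 - py) * 0.75          # ankles ahead of pelvis when seated

  ankle_L <- cbind(-width / 2 + px * 0, 0.08 + numeric(ns), pz + sep / 2 + c_off)
  ankle_R <- cbind(width / 2 + numeric(ns), 0.08 + numeric(ns), pz - sep / 2 + c_off)
  hip_L <- cbind(px - 0.09, py - 0.08, pz)
  hip_R <- cbind(px + 0.09, py - 0.08, pz)

  # knee angle target per frame: posture baseline tied to pelvis height,
  # overridden by the sampled walking / turning knee angles
  theta_base <- 95 + 77 * (py - 0.55) / 0.40
  theta_L <- theta_base
  theta_R <- theta_base
  walk_frames <- in_f | in_b
  theta_R[walk_frames] <- knee_walk + 4 * sin(2 * pi * k[walk_frames])
  theta_L[walk_frames] <- knee_walk + 4 * sin(2 * pi * k[walk_frames] + pi)
  theta_L[in_turn] <- knee_turn
  theta_R[in_turn] <- knee_turn
  theta_L <- pmin(pmax(theta_L, 91), 179)
  theta_R <- pmin(pmax(theta_R, 91), 179)

  knee_L <- pose_knee(hip_L, ankle_L, theta_L)
  knee_R <- pose_knee(hip_R, ankle_R, theta_R)
  foot_L <- ankle_L + matrix(rep(c(0, -0.04, 0.12), each = ns), ncol = 3)
  foot_R <- ankle_R + matrix(rep(c(0, -0.04, 0.12), each = ns), ncol = 3)

  pelvis <- cbind(px, py, pz)
  upper <- list(
    `1` = c(0, 0.25, 0), `2` = c(0, 0.55, 0), `3` = c(0, 0.70, 0),
    `4` = c(-0.18, 0.45, 0), `5` = c(-0.25, 0.25, 0.02),
    `6` = c(-0.28, 0.05, 0.05), `7` = c(-0.29, 0.00, 0.08),
    `8` = c(0.18, 0.45, 0), `9` = c(0.25, 0.25, 0.02),
    `10` = c(0.28, 0.05, 0.05), `11` = c(0.29, 0.00, 0.08),
    `20` = c(0, 0.45, 0), `21` = c(-0.30, -0.04, 0.10),
    `22` = c(-0.27, -0.02, 0.10), `23` = c(0.30, -0.04, 0.10),
    `24` = c(0.27, -0.02, 0.10)
  )

  joints <- matrix(0, nrow = ns, ncol = 75)
  put <- function(j, xyz) {
    joints[, (3 * j + 1):(3 * j + 3)] <<- xyz
  }
  put(0, pelvis)
  for (j in names(upper)) {
    put(as.integer(j), pelvis + matrix(rep(upper[[j]], each = ns), ncol = 3))
  }
  put(12, hip_L); put(16, hip_R)
  put(13, knee_L); put(17, knee_R)
  put(14, ankle_L); put(18, ankle_R)
  put(15, foot_L); put(19, foot_R)
  joints <- joints + matrix(rnoise(ns * 75, skel_noise_sd), nrow = ns)

  skeleton <- skeleton_recording(t = ts, joints = joints, rate = skel_rate)

  truth <- structure(list(
    boundaries = list(
      sit_to_stand = c(t0, t1), walk_forward = c(t1, t2), turn = c(t2, t3),
      walk_back = c(t3, t4), turn_to_sit = c(t4, t5)
    ),
    tug_start = t0, tug_end = t5,
    step_events = list(
      walk_forward = t1 + (seq_len(n_fwd) - 0.5) * sdur,
      walk_back = t3 + (seq_len(n_back) - 0.5) * sdur
    ),
    true_step_count = n_steps,
    subject_params = list(
      step_length = L, realized_step_length = 6 / n_steps,
      step_width = width, step_duration = sdur,
      turn_max_yaw = yaw_turn, turn_to_sit_max_yaw = yaw_tts,
      knee_angle_walk = knee_walk, knee_angle_turn = knee_turn,
      pelvic_pitch_offset_turn = p$pelvic_pitch_offset_turn,
      walk_pitch_rms = pitch_rms
    )
  ), class = "tug_truth")

  list(imu = imu, skeleton = skeleton, truth = truth)
}

# Place the knee so the angle at the knee between (knee->hip) and
# (knee->ankle) equals theta (degrees), bowing forward along +z.
# Rows of hip/ankle are frames.
pose_knee <- function(hip, ankle, theta) {
  d_ha <- ankle - hip
  c_len <- sqrt(rowSums(d_ha^2))
  c_len <- pmax(c_len, 1e-6)
  u <- d_ha / c_len
  # forward direction orthogonal to the hip->ankle axis
  fz <- cbind(-u[, 1] * u[, 3], -u[, 2] * u[, 3], 1 - u[, 3]^2)
  fn <- sqrt(rowSums(fz^2))
  fz <- fz / pmax(fn, 1e-9)
  d <- (c_len / 2) / tan(theta * pi / 360)  # theta/2 in radians
  (hip + ankle) / 2 + fz * d
}

#' Sample a synthetic two-cohort study
#'
#' Draws `n_low` low-fall-risk and `n_high` high-fall-risk subjects.
#' Demographics are drawn per group: age from the profile's normal
#' distribution truncated at 65 years, walking assistance and gender as
#' Bernoulli draws, and a BBS (Berg Balance Scale) score consistent with
#' the group label under the > 50 cutoff (low risk iff BBS > 50). Each
#' subject then gets one simulated trial via [simulate_trial()].
#'
#' @param n_low,n_high group sizes (each >= 1). The modeled study used
#'   26 low-risk and 15 high-risk participants.
#' @param profiles list with `low` and `high` [gait_profile()]s
#'   (default [default_profiles()]).
#' @param demographic_config optional list with `low`/`high` sublists
#'   overriding `age_mean_sd`, `assistance_prob`, `prop_male`.
#' @param seed integer master seed; subject-level seeds are derived from it.
#' @param rate,skel_rate,skel_noise_sd passed to [simulate_trial()].
#' @return a `tug_cohort`: list of records with `meta`, `imu`, `skeleton`,
#'   `truth`, ordered low group first, subject ids `S001, S002, ...`.
#' @examples
#' coh <- sample_cohort(3, 2, seed = 7)
#' length(coh)
#' @export
sample_cohort <- function(n_low, n_high, profiles = default_profiles(),
                          demographic_config = NULL, seed = 1,
                          rate = 5, skel_rate = 30, skel_noise_sd = 0.005) {
  if (n_low < 1 || n_high < 1) {
    tug_stop("tug_validation_error", "need n_low >= 1 and n_high >= 1")
  }
  labels <- c(rep("low", n_low), rep("high", n_high))
  demo <- list(
    low = list(age_mean_sd = profiles$low$age_mean_sd,
               assistance_prob = profiles$low$assistance_prob,
               prop_male = profiles$low$prop_male),
    high = list(age_mean_sd = profiles$high$age_mean_sd,
                assistance_prob = profiles$high$assistance_prob,
                prop_male = profiles$high$prop_male)
  )
  if (!is.null(demographic_config)) {
    for (g in intersect(names(demographic_config), c("low", "high"))) {
      demo[[g]] <- modifyList(demo[[g]], demographic_config[[g]])
    }
  }
  meta <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_along(labels), function(i) {
      g <- labels[i]
      d <- demo[[g]]
      data.frame(
        subject_id = sprintf("S%03d", i),
        age = round(rnorm_trunc(1, d$age_mean_sd[1], d$age_mean_sd[2], 65, Inf), 1),
        gender = if (runif(1) < d$prop_male) "M" else "F",
        assistance = if (runif(1) < d$assistance_prob) "yes" else "no",
        bbs = if (g == "low") sample(51:56, 1) else sample(28:50, 1),
        label = g,
        stringsAsFactors = FALSE
      )
    }))
  })
  cohort <- lapply(seq_along(labels), function(i) {
    trial <- simulate_trial(
      profiles[[labels[i]]],
      seed = (as.numeric(seed) * 10007 + i) %% 2147483647,
      rate = rate, skel_rate = skel_rate, skel_noise_sd = skel_noise_sd
    )
    list(meta = meta[i, , drop = FALSE], imu = trial$imu,
         skeleton = trial$skeleton, truth = trial$truth)
  })
  structure(cohort, class = "tug_cohort")
}
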