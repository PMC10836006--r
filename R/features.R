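# 142-parameter feature extraction from a segmented TUG trial.
#
# Layout (142 = 8 + 66 + 54 + 10 + 1 + 3):
#   temporal (8): duration + percentage of duration (POD) for each of the
#     four analysis subtasks (sit-to-stand, merged walk, turn, turn-to-sit);
#   acceleration (3 axes x 22): per-subtask statistic sets on V/ML/AP;
#   angular velocity (3 axes x 18): per-subtask sets on yaw/pitch/roll;
#   key-point (10): legs angle + both knee angles for walk and turn, plus
#     step counts / length / duration / width;
#   TUG duration (1); demographics (3): age, gender, assistance.

acc_stat_sets <- function() list(
  sit_to_stand = c("max", "min", "range", "rms", "max_jerk", "mean_jerk"),
  walk = c("range", "rms", "median", "cv"),
  turn = c("range", "rms", "median", "cv"),
  turn_to_sit = c("max", "min", "range", "rms", "median", "cv",
                  "max_jerk", "mean_jerk")
)

gyr_stat_sets <- function() list(
  sit_to_stand = c("max", "min", "range", "rms"),
  walk = c("range", "rms", "median", "cv"),
  turn = c("range", "rms", "median", "cv"),
  turn_to_sit = c("max", "min", "range", "rms", "median", "cv")
)

#' Canonical feature-name schema
#'
#' Returns the 142 feature names in their stable order. Sensor features are
#' named `{signal}_{stat}_{axis}_{subtask}`; the schema is bijective (142
#' unique names).
#'
#' @return character vector of length 142.
#' @export
feature_names <- function() {
  subtasks <- c("sit_to_stand", "walk", "turn", "turn_to_sit")
  temporal <- as.vector(t(outer(c("temporal_duration", "temporal_pod"),
                                subtasks, paste, sep = "_")))
  acc <- unlist(lapply(subtasks, function(st) {
    as.vector(t(outer(acc_stat_sets()[[st]], c("V", "ML", "AP"),
                      function(s, a) paste("acc", s, a, st, sep = "_"))))
  }))
  gyr <- unlist(lapply(subtasks, function(st) {
    as.vector(t(outer(gyr_stat_sets()[[st]], c("yaw", "pitch", "roll"),
                      function(s, a) paste("gyr", s, a, st, sep = "_"))))
  }))
  keypoint <- c(
    "keypoint_legs_angle_walk", "keypoint_left_knee_angle_walk",
    "keypoint_right_knee_angle_walk",
    "keypoint_legs_angle_turn", "keypoint_left_knee_angle_turn",
    "keypoint_right_knee_angle_turn",
    "keypoint_step_counts_walk", "keypoint_step_length_walk",
    "keypoint_step_duration_walk", "keypoint_step_width_walk"
  )
  c(temporal, acc, gyr, keypoint, "temporal_tug_duration",
    "age", "gender", "assistance")
}

#' Per-subtask summary statistics
#'
#' @param series numeric vector (length >= 2).
#' @return named list: `max`, `min`, `median`, `range` (max - min), `rms`
#'   (root mean square), `cv` (signed coefficient of variation: sample SD
#'   with n-1 denominator divided by the mean; `NA` with a warning when the
#'   mean is exactly zero).
#' @examples
#' summary_stats(c(1, 2, 3))  # median 2, range 2, cv 0.5
#' @export
summary_stats <- function(series) {
  if (length(series) < 2L) {
    tug_stop("tug_feature_error", "summary_stats needs >= 2 samples")
  }
  m <- mean(series)
  cv <- if (m == 0) {
    warning("coefficient of variation undefined: mean is exactly zero")
    NA_real_
  } else {
    sd(series) / m
  }
  list(max = max(series), min = min(series), median = median(series),
       range = max(series) - min(series),
       rms = sqrt(mean(series^2)), cv = cv)
}

#' Jerk statistics of an acceleration series
#'
#' Jerk is computed as successive absolute differences of the acceleration
#' samples, |a[i+1] - a[i]|, and reported in the acceleration unit (no
#' division by the sampling interval). Set `per_second = TRUE` for a true
#' time-derivative jerk.
#'
#' @param acc_series numeric acceleration series (length >= 2).
#' @param per_second divide differences by `dt` (default `FALSE`).
#' @param dt sampling interval in seconds (required if `per_second`).
#' @return named list with `max_jerk` and `mean_jerk`.
#' @examples
#' jerk_stats(c(0, 1, 3))  # max 2, mean 1.5
#' @export
jerk_stats <- function(acc_series, per_second = FALSE, dt = NULL) {
  if (length(acc_series) < 2L) {
    tug_stop("tug_feature_error", "jerk_stats needs >= 2 samples")
  }
  d <- abs(diff(acc_series))
  if (per_second) {
    if (is.null(dt) || dt <= 0) {
      tug_stop("tug_feature_error", "per_second jerk needs a positive dt")
    }
    d <- d / dt
  }
  list(max_jerk = max(d), mean_jerk = mean(d))
}

#' Temporal features of a segmented trial
#'
#' Durations of the four analysis subtasks (walking segments merged), their
#' percentages of duration (POD = subtask duration / TUG duration, in %),
#' and the TUG duration. Because the five raw subtasks tile the TUG, the
#' four PODs sum to exactly 100.
#'
#' @param intervals a `tug_intervals` object.
#' @return named numeric vector of 9 values (`temporal_*` names).
#' @export
temporal_features <- function(intervals) {
  stopifnot(inherits(intervals, "tug_intervals"))
  tug_dur <- intervals$tug_end - intervals$tug_start
  if (tug_dur <= 0) tug_stop("tug_feature_error", "zero TUG duration")
  dur <- c(
    sit_to_stand = intervals$sit_to_stand[2] - intervals$sit_to_stand[1],
    walk = merge_walking(intervals)$duration,
    turn = intervals$turn[2] - intervals$turn[1],
    turn_to_sit = intervals$turn_to_sit[2] - intervals$turn_to_sit[1]
  )
  out <- c(dur, 100 * dur / tug_dur, tug_dur)
  names(out) <- c(paste0("temporal_duration_", names(dur)),
                  paste0("temporal_pod_", names(dur)),
                  "temporal_tug_duration")
  out
}

# Angle in degrees between 3-D vectors stored as rows of matrices a and b.
vec_angle_deg <- function(a, b) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  cosv <- rowSums(a * b) / (na * nb)
  out <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  out[na < 1e-9 | nb < 1e-9] <- NA_real_
  out
}

frame_joints <- function(frame) {
  if (is.matrix(frame) && all(dim(frame) == c(25L, 3L))) return(frame)
  if (length(frame) == 75L) return(matrix(as.numeric(frame), ncol = 3, byrow = TRUE))
  tug_stop("tug_feature_error", "frame must be 25 x 3 or a 75-vector")
}

#' Legs angle and knee angles of one skeleton frame
#'
#' The legs angle is the angle between the vectors joint 0 (spine base) ->
#' joint 17 (right knee) and joint 0 -> joint 13 (left knee). The right
#' knee angle is the angle at joint 17 between the vectors 17 -> 16 (hip)
#' and 17 -> 18 (ankle); the left knee angle is mirrored through joints
#' 13, 12 and 14. 180 degrees is a fully extended leg.
#'
#' @param frame one skeleton frame: a 25 x 3 matrix or a 75-vector in
#'   `j00_x, j00_y, j00_z, ...` order.
#' @return angle in degrees in `[0, 180]` (`NA` with a warning for a
#'   degenerate zero-length vector).
#' @examples
#' f <- matrix(0, 25, 3)
#' f[14, ] <- c(-0.1, -0.5, 0)  # joint 13 (left knee; 1-based row 14)
#' f[18, ] <- c(0.1, -0.5, 0)   # joint 17 (right knee)
#' legs_angle(f)                # ~22.62 degrees
#' @export
legs_angle <- function(frame) {
  j <- frame_joints(frame)
  a <- vec_angle_deg(rbind(j[18, ] - j[1, ]), rbind(j[14, ] - j[1, ]))
  if (is.na(a)) warning("legs_angle: zero-length vector, frame skipped")
  a
}

#' @param side `"right"` (joints 17-16, 17-18) or `"left"` (13-12, 13-14).
#' @rdname legs_angle
#' @export
knee_angle <- function(frame, side = c("right", "left")) {
  side <- match.arg(side)
  j <- frame_joints(frame)
  idx <- if (side == "right") c(18L, 17L, 19L) else c(14L, 13L, 15L)  # 1-based
  a <- vec_angle_deg(rbind(j[idx[2], ] - j[idx[1], ]),
                     rbind(j[idx[3], ] - j[idx[1], ]))
  if (is.na(a)) warning("knee_angle: zero-length vector, frame skipped")
  a
}

# Vectorized angle series over a skeleton recording.
angle_series <- function(skeleton, which = c("legs", "left_knee", "right_knee")) {
  which <- match.arg(which)
  J <- skeleton$joints
  g <- function(j) J[, (3 * j + 1):(3 * j + 3), drop = FALSE]
  switch(which,
    legs = vec_angle_deg(g(17) - g(0), g(13) - g(0)),
    right_knee = vec_angle_deg(g(16) - g(17), g(18) - g(17)),
    left_knee = vec_angle_deg(g(12) - g(13), g(14) - g(13))
  )
}

#' Step metrics from the skeleton stream
#'
#' Steps are detected as local extrema of the signed AP-axis ankle
#' separation (left ankle joint 14 minus right ankle joint 18), with a
#' minimum prominence and spacing; each maximum and each minimum counts as
#' one step (left and right). Step length is the fixed total walking
#' distance (6 m) divided by the step count; step duration is the merged
#' walking duration divided by the step count; step width is the mean
#' ML-axis distance between the two ankles over the walking frames.
#'
#' @param skeleton a `tug_skeleton`.
#' @param intervals a `tug_intervals` (or list of two walking intervals).
#' @param total_distance walked distance in meters (default 6).
#' @param min_prominence minimum extremum prominence in meters.
#' @param min_spacing minimum time between same-signed extrema, seconds.
#' @param ap_axis,ml_axis coordinate axes holding the walking direction and
#'   the lateral direction (`"x"`, `"y"` or `"z"`).
#' @param foot_joints pair of joint indices used for both separations
#'   (default ankles `c(14, 18)`; use `c(15, 19)` for the foot joints).
#' @return named list: `step_counts`, `step_length`, `step_duration`,
#'   `step_width`, plus `step_events` (times of detected extrema).
#' @export
step_metrics <- function(skeleton, intervals, total_distance = 6,
                         min_prominence = 0.05, min_spacing = 0.3,
                         ap_axis = "z", ml_axis = "x",
                         foot_joints = c(14L, 18L)) {
  stopifnot(inherits(skeleton, "tug_skeleton"))
  walk <- if (inherits(intervals, "tug_intervals")) {
    merge_walking(intervals)$segments
  } else if (inherits(intervals, "tug_walk_phase")) {
    intervals$segments
  } else intervals
  t <- skeleton$t
  sep <- skeleton$joints[, joint_col(foot_joints[1], ap_axis)] -
    skeleton$joints[, joint_col(foot_joints[2], ap_axis)]
  wid <- abs(skeleton$joints[, joint_col(foot_joints[1], ml_axis)] -
               skeleton$joints[, joint_col(foot_joints[2], ml_axis)])
  spacing <- max(1L, as.integer(ceiling(min_spacing * skeleton$rate)))
  events <- numeric(0)
  walk_dur <- 0
  any_frames <- FALSE
  for (iv in walk) {
    walk_dur <- walk_dur + (iv[2] - iv[1])
    sel <- which(t >= iv[1] & t < iv[2])
    if (length(sel) < 3L) next
    any_frames <- TRUE
    xi <- sep[sel]
    pk <- c(find_peaks(xi, min_prominence, spacing),
            find_peaks(-xi, min_prominence, spacing))
    events <- c(events, t[sel][pk])
  }
  if (!any_frames) tug_stop("tug_feature_error", "no gait detected: walk intervals empty")
  events <- sort(events)
  n_steps <- length(events)
  if (n_steps == 0L) tug_stop("tug_feature_error", "no gait detected: zero steps")
  in_walk <- in_intervals(t, walk)
  list(
    step_counts = n_steps,
    step_length = total_distance / n_steps,
    step_duration = walk_dur / n_steps,
    step_width = mean(wid[in_walk]),
    step_events = events
  )
}

#' Extract the 142-parameter feature vector
#'
#' Computes every parameter of the feature schema (see [feature_names()])
#' from a segmented trial: per-subtask acceleration and angular-velocity
#' statistics, temporal durations and PODs, key-point angles and step
#' metrics, TUG duration, and demographics (coded gender M=1/F=0,
#' assistance yes=1/no=0). Subtasks with fewer than two samples yield `NA`
#' features and mark the vector incomplete.
#'
#' @param imu a `tug_imu`.
#' @param skeleton a `tug_skeleton` on the same clock.
#' @param intervals a `tug_intervals` (e.g. from [segment_subtasks()]).
#' @param meta optional one-row data frame with `age`, `gender`,
#'   `assistance` (otherwise those features are `NA`).
#' @param step_options list of overrides passed to [step_metrics()].
#' @return named numeric vector of length 142 with attribute `incomplete`
#'   (`TRUE` if any subtask had insufficient samples).
#' @examples
#' trial <- simulate_trial(default_profiles()$low, seed = 5)
#' fv <- extract_features(trial$imu, trial$skeleton,
#'                        segment_subtasks(trial$imu))
#' length(fv)  # 142
#' @export
extract_features <- function(imu, skeleton, intervals, meta = NULL,
                             step_options = list()) {
  stopifnot(inherits(imu, "tug_imu"), inherits(skeleton, "tug_skeleton"),
            inherits(intervals, "tug_intervals"))
  out <- stats::setNames(rep(NA_real_, length(feature_names())), feature_names())
  incomplete <- FALSE

  phases <- list(
    sit_to_stand = list(intervals$sit_to_stand),
    walk = merge_walking(intervals)$segments,
    turn = list(intervals$turn),
    turn_to_sit = list(intervals$turn_to_sit)
  )
  imu_idx <- lapply(phases, function(iv) which(in_intervals(imu$t, iv)))
  skel_idx <- lapply(phases, function(iv) which(in_intervals(skeleton$t, iv)))

  series <- list(
    acc = list(V = imu$acc$V, ML = imu$acc$ML, AP = imu$acc$AP),
    gyr = list(yaw = imu$gyr$yaw, pitch = imu$gyr$pitch, roll = imu$gyr$roll)
  )
  sets <- list(acc = acc_stat_sets(), gyr = gyr_stat_sets())
  for (sig in c("acc", "gyr")) {
    for (st in names(phases)) {
      sel <- imu_idx[[st]]
      stats_wanted <- sets[[sig]][[st]]
      for (axis in names(series[[sig]])) {
        nm <- paste(sig, stats_wanted, axis, st, sep = "_")
        if (length(sel) < 2L) {
          incomplete <- TRUE
          next
        }
        x <- series[[sig]][[axis]][sel]
        ss <- summary_stats(x)
        if (any(c("max_jerk", "mean_jerk") %in% stats_wanted)) {
          ss <- c(ss, jerk_stats(x))
        }
        out[nm] <- unlist(ss[stats_wanted], use.names = FALSE)
      }
    }
  }

  out[names(temporal_features(intervals))] <- temporal_features(intervals)

  ang <- list(
    legs_angle = angle_series(skeleton, "legs"),
    left_knee_angle = angle_series(skeleton, "left_knee"),
    right_knee_angle = angle_series(skeleton, "right_knee")
  )
  for (st in c("walk", "turn")) {
    sel <- skel_idx[[st]]
    if (length(sel) < 2L) {
      incomplete <- TRUE
      next
    }
    for (a in names(ang)) {
      out[paste0("keypoint_", a, "_", st)] <- mean(ang[[a]][sel], na.rm = TRUE)
    }
  }

  sm <- do.call(step_metrics, c(list(skeleton = skeleton, intervals = intervals),
                                step_options))
  out["keypoint_step_counts_walk"] <- sm$step_counts
  out["keypoint_step_length_walk"] <- sm$step_length
  out["keypoint_step_duration_walk"] <- sm$step_duration
  out["keypoint_step_width_walk"] <- sm$step_width

  if (!is.null(meta)) {
    out["age"] <- as.numeric(meta$age)
    out["gender"] <- as.numeric(meta$gender %in% c("M", "m", 1))
    out["assistance"] <- as.numeric(meta$assistance %in% c("yes", "y", 1))
  }
  attr(out, "incomplete") <- incomplete
  if (incomplete) warning("feature vector incomplete: a subtask had < 2 samples")
  out
}

#' Feature table for a whole cohort
#'
#' Runs segmentation and feature extraction for every subject of a cohort
#' and binds the results into one data frame (one row per subject: id,
#' label, then the 142 features).
#'
#' @param cohort a `tug_cohort`.
#' @param control a [seg_control()].
#' @param step_options passed to [step_metrics()].
#' @return data frame with `subject_id`, `label` and 142 feature columns.
#' @export
cohort_features <- function(cohort, control = seg_control(),
                            step_options = list()) {
  mat <- t(vapply(cohort, function(rec) {
    iv <- segment_subtasks(rec$imu, control = control)
    extract_features(rec$imu, rec$skeleton, iv, rec$meta,
                     step_options = step_options)
  }, numeric(length(feature_names()))))
  out <- data.frame(
    subject_id = vapply(cohort, function(r) as.character(r$meta$subject_id),
                        character(1)),
    label = vapply(cohort, function(r) as.character(r$meta$label), character(1)),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(mat, check.names = FALSE))
}
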