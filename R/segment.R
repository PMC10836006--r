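# TUG subtask segmentation from gyroscope angular velocity.
#
# Principle: the seated lead-in/out is quiescent, which identifies test
# initiation and termination from a baseline-derived activity threshold;
# the pitch axis bursts during sit-to-stand and stand-to-sit; the yaw axis
# peaks during the two 180-degree turns; both are quiet while walking.

#' Segmentation tuning parameters
#'
#' All thresholds are relative (baseline-derived or fractions of event
#' peaks), so segmentation is invariant to rescaling the gyro channels.
#'
#' @param smooth_window moving-average window in seconds applied to each
#'   gyro channel before thresholding.
#' @param baseline_window seconds of initial sitting used to estimate the
#'   quiescent baseline.
#' @param thresh_k activity threshold = baseline mean + `thresh_k` x
#'   baseline SD of the smoothed angular speed.
#' @param min_active minimum supra-threshold duration (s) for activity to
#'   count as TUG start/end.
#' @param peak_fraction a yaw/pitch event extends over the region where the
#'   smoothed absolute signal exceeds `peak_fraction` x its peak.
#' @return a list of class `tug_seg_control`.
#' @export
seg_control <- function(smooth_window = 0.6, baseline_window = 1.0,
                        thresh_k = 4, min_active = 0.4, peak_fraction = 0.2) {
  stopifnot(smooth_window >= 0, baseline_window > 0, thresh_k >= 0,
            min_active >= 0, peak_fraction > 0, peak_fraction < 1)
  structure(list(smooth_window = smooth_window,
                 baseline_window = baseline_window,
                 thresh_k = thresh_k, min_active = min_active,
                 peak_fraction = peak_fraction),
            class = "tug_seg_control")
}

# Accept either (tug_imu) or (yaw, pitch, t) argument styles.
seg_inputs <- function(yaw, pitch, t) {
  if (inherits(yaw, "tug_imu")) {
    list(yaw = yaw$gyr$yaw, pitch = yaw$gyr$pitch, t = yaw$t)
  } else {
    stopifnot(length(yaw) == length(t), length(pitch) == length(t))
    list(yaw = as.numeric(yaw), pitch = as.numeric(pitch), t = as.numeric(t))
  }
}

# Linear interpolation of the time where series x crosses level `thr`
# between samples i and i+1 (rising if x[i] < thr <= x[i+1]).
cross_time <- function(t, x, i, thr) {
  if (i < 1L) return(t[1])
  if (i >= length(t)) return(t[length(t)])
  x0 <- x[i]; x1 <- x[i + 1L]
  if (!is.finite(x0) || !is.finite(x1) || x1 == x0) return(t[i + 1L])
  t[i] + (thr - x0) / (x1 - x0) * (t[i + 1L] - t[i])
}

#' Detect TUG start and end from quiescent sitting baselines
#'
#' The smoothed combined angular speed sqrt(yaw^2 + pitch^2) is compared
#' against an activity threshold estimated from the initial sitting
#' baseline; the TUG spans the first to the last crossing that stays
#' supra-threshold for at least `min_active` seconds. Crossing times are
#' linearly interpolated between samples.
#'
#' @param yaw a `tug_imu` recording, or the yaw angular-velocity series
#'   (deg/s).
#' @param pitch pitch angular-velocity series (ignored when `yaw` is a
#'   `tug_imu`).
#' @param t timestamps in seconds (ignored when `yaw` is a `tug_imu`).
#' @param control a [seg_control()].
#' @return list with `tug_start`, `tug_end` (seconds) and the detection
#'   internals (`threshold`, `rate`).
#' @export
detect_bounds <- function(yaw, pitch = NULL, t = NULL, control = seg_control()) {
  s <- seg_inputs(yaw, pitch, t)
  n <- length(s$t)
  if (n < 4L) tug_stop("tug_segmentation_error", "recording too short")
  rate <- 1 / median(diff(s$t))
  sm_yaw <- smooth_ma(s$yaw, control$smooth_window, rate)
  sm_pitch <- smooth_ma(s$pitch, control$smooth_window, rate)
  speed <- sqrt(sm_yaw^2 + sm_pitch^2)

  # baseline statistics from the raw (unsmoothed) speed: with few samples in
  # the baseline window the smoothed series grossly understates the noise SD
  nb <- max(2L, sum(s$t <= s$t[1] + control$baseline_window))
  raw_speed <- sqrt(s$yaw^2 + s$pitch^2)
  thr <- mean(raw_speed[1:nb]) + control$thresh_k * sd(raw_speed[1:nb])

  active <- speed > thr
  min_run <- max(1L, as.integer(ceiling(control$min_active * rate)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_run)
  # a qualifying run must clearly exceed the threshold, not merely graze it:
  # this rejects rare noise excursions without an absolute scale
  ok <- ok[vapply(ok, function(k) max(speed[starts[k]:ends[k]]) >= 2 * thr,
                  logical(1))]
  if (!length(ok)) tug_stop("tug_no_tug", "no TUG detected")
  i_first <- starts[ok[1]]
  i_last <- ends[ok[length(ok)]]
  if (i_first == 1L || i_last == n) {
    tug_stop("tug_no_baseline", "no pre/post baseline: activity reaches the recording edge")
  }
  tug_start <- cross_time(s$t, speed, i_first - 1L, thr)
  tug_end <- cross_time(s$t, -speed, i_last, -thr)
  # quiescent sitting must precede the detected activity
  if (tug_start - s$t[1] < control$baseline_window) {
    tug_stop("tug_no_baseline", "no pre/post baseline: activity reaches the recording edge")
  }
  list(tug_start = tug_start, tug_end = tug_end, threshold = thr, rate = rate)
}

#' Five-subtask intervals container
#'
#' Half-open, contiguous intervals `[start, end)` for sit-to-stand, walk
#' forward, turn, walk back and turn-to-sit. `tug_start` equals the
#' sit-to-stand start and `tug_end` the turn-to-sit end, so the five
#' durations sum exactly to the TUG duration.
#'
#' @param sit_to_stand,walk_forward,turn,walk_back,turn_to_sit numeric
#'   `c(start, end)` pairs in seconds.
#' @return an object of class `tug_intervals`.
#' @export
subtask_intervals <- function(sit_to_stand, walk_forward, turn, walk_back,
                              turn_to_sit) {
  iv <- list(sit_to_stand = as.numeric(sit_to_stand),
             walk_forward = as.numeric(walk_forward),
             turn = as.numeric(turn),
             walk_back = as.numeric(walk_back),
             turn_to_sit = as.numeric(turn_to_sit))
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[2] <= v[1]) {
      tug_stop("tug_segmentation_error",
               "segmentation inconsistent: interval '%s' not positive", nm)
    }
  }
  for (i in 1:4) {
    if (abs(iv[[i]][2] - iv[[i + 1]][1]) > 1e-9) {
      tug_stop("tug_segmentation_error",
               "segmentation inconsistent: intervals not contiguous at '%s'",
               names(iv)[i + 1])
    }
    iv[[i + 1]][1] <- iv[[i]][2]  # enforce exact contiguity
  }
  structure(c(iv, list(tug_start = iv$sit_to_stand[1],
                       tug_end = iv$turn_to_sit[2])),
            class = "tug_intervals")
}

#' Segment a TUG recording into its five subtasks
#'
#' Within the bounds from [detect_bounds()], the two largest smoothed
#' |yaw| peaks anchor, in time order, the mid-test turn and the final
#' turn-to-sit; each yaw event extends over the surrounding region where
#' the smoothed |yaw| exceeds `peak_fraction` of its peak. Sit-to-stand
#' ends where the initial pitch burst falls below the same fraction of its
#' own peak. The walking segments fill the gaps. Equal peaks are broken by
#' earlier time.
#'
#' @inheritParams detect_bounds
#' @return a [subtask_intervals()] object.
#' @examples
#' trial <- simulate_trial(default_profiles()$low, seed = 3)
#' iv <- segment_subtasks(trial$imu)
#' iv$turn
#' @export
segment_subtasks <- function(yaw, pitch = NULL, t = NULL,
                             control = seg_control()) {
  s <- seg_inputs(yaw, pitch, t)
  bounds <- detect_bounds(s$yaw, s$pitch, s$t, control)
  rate <- bounds$rate
  sm_yaw <- abs(smooth_ma(s$yaw, control$smooth_window, rate))
  sm_pitch <- abs(smooth_ma(s$pitch, control$smooth_window, rate))
  inb <- s$t >= bounds$tug_start & s$t <= bounds$tug_end
  idx <- which(inb)

  ev1 <- yaw_event(s$t, sm_yaw, idx, control$peak_fraction)
  # mask the first event (with margin) and find the second-largest peak
  margin <- as.integer(round(0.5 * rate))
  masked <- sm_yaw
  lo <- max(1L, ev1$i_lo - margin)
  hi <- min(length(masked), ev1$i_hi + margin)
  masked[lo:hi] <- 0
  if (max(masked[idx]) <= max(bounds$threshold, 1e-12)) {
    tug_stop("tug_segmentation_error", "turn not found: fewer than two yaw peaks")
  }
  ev2 <- yaw_event(s$t, masked, idx, control$peak_fraction, ref = sm_yaw)
  if (ev1$t_peak == ev2$t_peak) {
    tug_stop("tug_segmentation_error", "turn not found: fewer than two yaw peaks")
  }
  turn_ev <- if (ev1$t_peak < ev2$t_peak) ev1 else ev2
  tts_ev <- if (ev1$t_peak < ev2$t_peak) ev2 else ev1

  # initial pitch burst: dominant excursion between tug_start and the turn
  pre <- which(s$t >= bounds$tug_start & s$t < turn_ev$t_lo)
  if (!length(pre)) {
    tug_stop("tug_segmentation_error", "sit-to-stand not found: no pitch burst")
  }
  p_peak <- max(sm_pitch[pre])
  if (p_peak <= bounds$threshold) {
    tug_stop("tug_segmentation_error", "sit-to-stand not found: no pitch burst")
  }
  ip <- pre[which.max(sm_pitch[pre])]
  p_thr <- control$peak_fraction * p_peak
  j <- ip
  while (j < length(s$t) && sm_pitch[j] > p_thr) j <- j + 1L
  sts_end <- cross_time(s$t, -sm_pitch, j - 1L, -p_thr)

  b <- c(bounds$tug_start, sts_end, turn_ev$t_lo, turn_ev$t_hi,
         tts_ev$t_lo, bounds$tug_end)
  if (any(diff(b) <= 0)) {
    tug_stop("tug_segmentation_error",
             "segmentation inconsistent: events out of order")
  }
  subtask_intervals(
    sit_to_stand = b[1:2], walk_forward = b[2:3], turn = b[3:4],
    walk_back = b[4:5], turn_to_sit = b[5:6]
  )
}

# Locate the largest peak of `sm` restricted to idx and its peak_fraction
# extent (interpolated). `ref` supplies the unmasked series for extent
# walking when `sm` has been masked.
yaw_event <- function(t, sm, idx, peak_fraction, ref = sm) {
  i_peak <- idx[which.max(sm[idx])]
  peak <- ref[i_peak]
  thr <- peak_fraction * peak
  i_lo <- i_peak
  while (i_lo > 1L && ref[i_lo - 1L] > thr) i_lo <- i_lo - 1L
  i_hi <- i_peak
  while (i_hi < length(ref) && ref[i_hi + 1L] > thr) i_hi <- i_hi + 1L
  t_lo <- cross_time(t, ref, i_lo - 1L, thr)
  t_hi <- cross_time(t, -ref, i_hi, -thr)
  list(i_peak = i_peak, t_peak = t[i_peak], peak = peak,
       i_lo = i_lo, i_hi = i_hi, t_lo = t_lo, t_hi = t_hi)
}

#' Merge the two walking segments into one walking phase
#'
#' Per-sample statistics over the walking phase pool the samples of both
#' segments; the phase duration is the sum of the two segment durations.
#'
#' @param intervals a `tug_intervals` object.
#' @return a list of class `tug_walk_phase` with `segments` (list of two
#'   `c(start, end)` intervals) and `duration` (seconds).
#' @export
merge_walking <- function(intervals) {
  stopifnot(inherits(intervals, "tug_intervals"))
  segs <- list(intervals$walk_forward, intervals$walk_back)
  structure(list(
    segments = segs,
    duration = sum(vapply(segs, function(v) v[2] - v[1], numeric(1)))
  ), class = "tug_walk_phase")
}

# Logical index of timestamps falling in interval(s) [start, end).
in_intervals <- function(t, intervals) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  if (inherits(intervals, "tug_walk_phase")) intervals <- intervals$segments
  out <- rep(FALSE, length(t))
  for (iv in intervals) out <- out | (t >= iv[1] & t < iv[2])
  out
}

#' @export
print.tug_intervals <- function(x, ...) {
  cat("<tug_intervals>\n")
  for (nm in c("sit_to_stand", "walk_forward", "turn", "walk_back", "turn_to_sit")) {
    cat(sprintf("  %-13s %7.3f - %7.3f s (%.3f s)\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][2] - x[[nm]][1]))
  }
  invisible(x)
}

#' Intervals to/from JSON
#'
#' @param intervals a `tug_intervals`.
#' @param path file path.
#' @return `read_intervals()` returns a `tug_intervals`.
#' @export
write_intervals <- function(intervals, path) {
  jsonlite::write_json(unclass(intervals), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subtask_intervals(x$sit_to_stand, x$walk_forward, x$turn, x$walk_back,
                    x$turn_to_sit)
}
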