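#' IMU recording container
#'
#' Builds a validated `tug_imu` object: a shared time axis, tri-axial
#' acceleration (vertical V, mediolateral ML, anterior-posterior AP, sensor
#' units where 1.0 is the upright gravity-inclusive baseline on V) and
#' tri-axial angular velocity (yaw, pitch, roll in deg/s, about the V, ML
#' and AP axes respectively).
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param acc data frame (or matrix) with columns `V`, `ML`, `AP`.
#' @param gyr data frame (or matrix) with columns `yaw`, `pitch`, `roll`.
#' @param rate nominal sampling rate in Hz (default: inferred from `t`).
#' @return an object of class `tug_imu`.
#' @export
imu_recording <- function(t, acc, gyr, rate = NULL) {
  acc <- as.data.frame(acc)
  gyr <- as.data.frame(gyr)
  if (!identical(names(acc), c("V", "ML", "AP"))) {
    tug_stop("tug_schema_error", "acc must have columns V, ML, AP")
  }
  if (!identical(names(gyr), c("yaw", "pitch", "roll"))) {
    tug_stop("tug_schema_error", "gyr must have columns yaw, pitch, roll")
  }
  n <- length(t)
  if (n < 2L) tug_stop("tug_schema_error", "recording needs >= 2 samples")
  if (nrow(acc) != n || nrow(gyr) != n) {
    tug_stop("tug_schema_error", "t, acc and gyr must have equal length")
  }
  check_time_axis(t, "imu")
  check_finite_frame(cbind(acc, gyr), "imu")
  if (is.null(rate)) rate <- 1 / median(diff(t))
  structure(list(t = as.numeric(t), acc = acc, gyr = gyr, rate = rate),
            class = "tug_imu")
}

#' Skeleton recording container
#'
#' Builds a validated `tug_skeleton` object holding per-frame 3-D positions
#' of the 25 depth-camera key points (Kinect v2 joint indexing: 0 spine
#' base/pelvis, 12/16 hips, 13/17 knees, 14/18 ankles, 15/19 feet, ...).
#'
#' @param t numeric vector of frame timestamps in seconds.
#' @param joints numeric matrix with `length(t)` rows and 75 columns named
#'   `j00_x, j00_y, j00_z, ..., j24_z` (meters; y is vertical).
#' @param rate nominal frame rate in Hz (default: inferred).
#' @return an object of class `tug_skeleton`.
#' @export
skeleton_recording <- function(t, joints, rate = NULL) {
  joints <- as.matrix(joints)
  if (ncol(joints) != 75L) {
    tug_stop("tug_schema_error",
             "skeleton needs 75 coordinate columns (25 joints x 3), got %d",
             ncol(joints))
  }
  colnames(joints) <- skeleton_cols()
  n <- length(t)
  if (n < 2L) tug_stop("tug_schema_error", "recording needs >= 2 samples")
  if (nrow(joints) != n) {
    tug_stop("tug_schema_error", "t and joints must have equal length")
  }
  check_time_axis(t, "skeleton")
  check_finite_frame(as.data.frame(joints), "skeleton")
  if (is.null(rate)) rate <- 1 / median(diff(t))
  structure(list(t = as.numeric(t), joints = joints, rate = rate),
            class = "tug_skeleton")
}

skeleton_cols <- function() {
  as.vector(t(outer(sprintf("j%02d", 0:24), c("x", "y", "z"), paste, sep = "_")))
}

# Column index of one coordinate of one joint in the 75-column layout.
joint_col <- function(joint, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  3L * joint + match(axis, c("x", "y", "z"))
}

check_time_axis <- function(t, what) {
  if (any(!is.finite(t))) {
    tug_stop("tug_schema_error", "%s: non-finite timestamp at row %d",
             what, which(!is.finite(t))[1])
  }
  d <- diff(t)
  if (any(d <= 0)) {
    tug_stop("tug_schema_error", "%s: time not strictly increasing at row %d",
             what, which(d <= 0)[1] + 1L)
  }
}

check_finite_frame <- function(df, what) {
  for (nm in names(df)) {
    bad <- which(!is.finite(df[[nm]]))
    if (length(bad)) {
      tug_stop("tug_schema_error", "%s: non-finite value in column '%s' row %d",
               what, nm, bad[1])
    }
  }
}

#' Read / write IMU CSV streams
#'
#' The on-disk format is a plain CSV with header
#' `t, acc_V, acc_ML, acc_AP, gyr_yaw, gyr_pitch, gyr_roll`
#' (seconds, sensor units, deg/s). `write_imu()` followed by `read_imu()`
#' reproduces the recording to full printed precision.
#'
#' @param path file path.
#' @return `read_imu()` returns a `tug_imu`; `write_imu()` returns `path`
#'   invisibly.
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) tug_stop("tug_io_error", "no such file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  want <- c("t", "acc_V", "acc_ML", "acc_AP", "gyr_yaw", "gyr_pitch", "gyr_roll")
  miss <- setdiff(want, names(df))
  if (length(miss)) {
    tug_stop("tug_schema_error", "imu file %s: missing column(s) %s",
             path, paste(miss, collapse = ", "))
  }
  imu_recording(
    t = df$t,
    acc = data.frame(V = df$acc_V, ML = df$acc_ML, AP = df$acc_AP),
    gyr = data.frame(yaw = df$gyr_yaw, pitch = df$gyr_pitch, roll = df$gyr_roll)
  )
}

#' @param rec a `tug_imu` object.
#' @rdname read_imu
#' @export
write_imu <- function(rec, path) {
  stopifnot(inherits(rec, "tug_imu"))
  df <- data.frame(
    t = rec$t,
    acc_V = rec$acc$V, acc_ML = rec$acc$ML, acc_AP = rec$acc$AP,
    gyr_yaw = rec$gyr$yaw, gyr_pitch = rec$gyr$pitch, gyr_roll = rec$gyr$roll
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write skeleton CSV streams
#'
#' CSV with header `t, j00_x, j00_y, j00_z, ..., j24_z` (76 columns;
#' seconds and meters).
#'
#' @param path file path.
#' @return `read_skeleton()` returns a `tug_skeleton`; `write_skeleton()`
#'   returns `path` invisibly.
#' @export
read_skeleton <- function(path) {
  if (!file.exists(path)) tug_stop("tug_io_error", "no such file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  want <- c("t", skeleton_cols())
  if (!identical(names(df), want)) {
    tug_stop("tug_schema_error",
             "skeleton file %s: expected 76 columns t, j00_x ... j24_z (got %d)",
             path, ncol(df))
  }
  skeleton_recording(t = df$t, joints = as.matrix(df[, -1]))
}

#' @param rec a `tug_skeleton` object.
#' @rdname read_skeleton
#' @export
write_skeleton <- function(rec, path) {
  stopifnot(inherits(rec, "tug_skeleton"))
  df <- data.frame(t = rec$t, rec$joints, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-trial ground truth JSON
#'
#' Ground truth (known only for simulated trials) stores the five phase
#' boundary times and the step-event times.
#'
#' @param truth a `tug_truth` list as produced by [simulate_trial()].
#' @param path file path.
#' @return `read_ground_truth()` returns a `tug_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "tug_truth")
}

#' Load a cohort directory
#'
#' Expects `subjects.csv` (columns `subject_id, age, gender, assistance,
#' bbs, label`) plus, per subject id, `<id>_imu.csv` and `<id>_skeleton.csv`
#' (and optionally `<id>_truth.json`). Subjects with a missing sensor file
#' are excluded with a warning each — never silently dropped — mirroring
#' real-cohort attrition. Output is sorted by subject id.
#'
#' @param directory path to the cohort directory.
#' @return a `tug_cohort`: list of records, each with elements `meta`
#'   (one-row data frame), `imu`, `skeleton` and `truth` (or `NULL`).
#' @export
load_cohort <- function(directory) {
  meta_path <- file.path(directory, "subjects.csv")
  if (!file.exists(meta_path)) {
    tug_stop("tug_io_error", "no subjects.csv in %s", directory)
  }
  meta <- read.csv(meta_path, check.names = FALSE)
  want <- c("subject_id", "age", "gender", "assistance", "bbs", "label")
  miss <- setdiff(want, names(meta))
  if (length(miss)) {
    tug_stop("tug_schema_error", "subjects.csv: missing column(s) %s",
             paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$subject_id)) {
    tug_stop("tug_schema_error", "duplicated subject_id: %s",
             meta$subject_id[duplicated(meta$subject_id)][1])
  }
  meta <- meta[order(meta$subject_id), , drop = FALSE]
  if (nrow(meta) == 0L) {
    warning("empty cohort: subjects.csv has no rows")
    return(structure(list(), class = "tug_cohort"))
  }
  records <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$subject_id[i]
    imu_path <- file.path(directory, paste0(id, "_imu.csv"))
    skel_path <- file.path(directory, paste0(id, "_skeleton.csv"))
    truth_path <- file.path(directory, paste0(id, "_truth.json"))
    missing_files <- c(
      if (!file.exists(imu_path)) "imu",
      if (!file.exists(skel_path)) "skeleton"
    )
    if (length(missing_files)) {
      warning(sprintf("subject %s excluded: missing %s file(s)",
                      id, paste(missing_files, collapse = " and ")),
              call. = FALSE)
      next
    }
    records[[length(records) + 1L]] <- list(
      meta = meta[i, , drop = FALSE],
      imu = read_imu(imu_path),
      skeleton = read_skeleton(skel_path),
      truth = if (file.exists(truth_path)) read_ground_truth(truth_path) else NULL
    )
  }
  structure(records, class = "tug_cohort")
}

#' Write a cohort to a directory
#'
#' Inverse of [load_cohort()]: writes `subjects.csv` plus per-subject IMU,
#' skeleton and (when present) ground-truth files.
#'
#' @param cohort a `tug_cohort` (e.g. from [sample_cohort()]).
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(cohort, `[[`, "meta"))
  write.csv(meta, file.path(directory, "subjects.csv"), row.names = FALSE)
  for (rec in cohort) {
    id <- rec$meta$subject_id
    write_imu(rec$imu, file.path(directory, paste0(id, "_imu.csv")))
    write_skeleton(rec$skeleton, file.path(directory, paste0(id, "_skeleton.csv")))
    if (!is.null(rec$truth)) {
      write_ground_truth(rec$truth, file.path(directory, paste0(id, "_truth.json")))
    }
  }
  invisible(directory)
}

#' @export
print.tug_imu <- function(x, ...) {
  cat(sprintf("<tug_imu> %d samples @ %.3g Hz, %.2f-%.2f s\n",
              length(x$t), x$rate, min(x$t), max(x$t)))
  invisible(x)
}

#' @export
print.tug_skeleton <- function(x, ...) {
  cat(sprintf("<tug_skeleton> %d frames @ %.3g Hz, 25 joints\n",
              length(x$t), x$rate))
  invisible(x)
}

#' @export
print.tug_cohort <- function(x, ...) {
  labs <- vapply(x, function(r) as.character(r$meta$label), character(1))
  cat(sprintf("<tug_cohort> %d subjects (%d low, %d high)\n",
              length(x), sum(labs == "low"), sum(labs == "high")))
  invisible(x)
}
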