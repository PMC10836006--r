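# End-to-end orchestration: simulate -> segment -> extract -> analyze,
# with explicit seeding, a manifest, and CSV/JSON artifacts only.

#' Build a run configuration
#'
#' All seeds are explicit; the configuration round-trips losslessly
#' through its JSON (or YAML, when the `yaml` package is installed) file
#' form via [write_run_config()] / [read_run_config()].
#'
#' @param n_low,n_high cohort sizes (defaults: the modeled 26 / 15 study).
#' @param seed master seed.
#' @param rate,skel_rate sampling rates in Hz.
#' @param profile_overrides optional list with `low`/`high` sublists of
#'   [gait_profile()] field overrides.
#' @param segmentation list of [seg_control()] overrides.
#' @param stats list of statistical options: `alpha`, `d_threshold`,
#'   `adjust` (`"none"` or `"BH"` for a Benjamini-Hochberg option).
#' @param out_dir output directory for [run_experiment()].
#' @param write_recordings also write per-subject sensor CSVs.
#' @return a list of class `tug_run_config`.
#' @export
run_config <- function(n_low = 26, n_high = 15, seed = 7,
                       rate = 5, skel_rate = 30,
                       profile_overrides = NULL,
                       segmentation = list(), stats = list(),
                       out_dir = tempfile("tugfall_run_"),
                       write_recordings = FALSE) {
  cfg <- list(
    n_low = as.integer(n_low), n_high = as.integer(n_high),
    seed = as.integer(seed), rate = rate, skel_rate = skel_rate,
    profile_overrides = profile_overrides,
    segmentation = segmentation,
    stats = modifyList(list(alpha = 0.05, d_threshold = 0.8, adjust = "none"),
                       stats),
    out_dir = out_dir, write_recordings = isTRUE(write_recordings)
  )
  validate_run_config(cfg)
  structure(cfg, class = "tug_run_config")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$n_low) || is.null(cfg$n_high) ||
      is.na(cfg$n_low) || is.na(cfg$n_high) ||
      cfg$n_low < 1L || cfg$n_high < 1L) {
    tug_stop("tug_validation_error", "config: need n_low >= 1 and n_high >= 1")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    tug_stop("tug_validation_error", "config: seed must be explicit")
  }
  if (cfg$rate <= 0 || cfg$skel_rate <= 0) {
    tug_stop("tug_validation_error", "config: rates must be positive")
  }
  invisible(cfg)
}

#' Read / write a run configuration file
#'
#' JSON is always supported; `.yaml`/`.yml` files additionally work when
#' the `yaml` package is installed.
#'
#' @param cfg a `tug_run_config`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_run_config()` returns a `tug_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      tug_stop("tug_io_error", "YAML config requires the 'yaml' package")
    }
    yaml::write_yaml(unclass(cfg), path)
  } else {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      tug_stop("tug_io_error", "YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

apply_profile_overrides <- function(profiles, overrides) {
  if (is.null(overrides)) return(profiles)
  for (g in intersect(names(overrides), c("low", "high"))) {
    p <- modifyList(unclass(profiles[[g]]), overrides[[g]])
    profiles[[g]] <- structure(p, class = "tug_profile")
    validate_profile(profiles[[g]])
  }
  profiles
}

#' Run one seeded end-to-end experiment
#'
#' Simulates a cohort, segments every trial, extracts the 142-parameter
#' feature table, runs the group comparison, the large-effect screen,
#' univariate logistic fits for the screened parameters, and the
#' three-feature-set ablation. Writes `features.csv`, `group_tests.csv`,
#' `screened.csv`, `univariate.csv`, `ablation.csv`, `roc_*.csv`, a
#' recovery summary and a JSON `manifest.json` (config + seed + package
#' version) to `cfg$out_dir`. Any stage failure aborts with the stage name
#' and subject id.
#'
#' @param cfg a [run_config()] (or a path to a config file).
#' @return invisibly, a list with `features`, `tests`, `screened`,
#'   `univariate`, `ablation`, `recovery`, `manifest`.
#' @export
run_experiment <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- apply_profile_overrides(default_profiles(), cfg$profile_overrides)
  control <- do.call(seg_control, cfg$segmentation)

  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e) {
      tug_stop("tug_stage_error", "stage '%s' failed for subject %s: %s",
               name, subject, conditionMessage(e))
    })
  }

  cohort <- stage("simulate", "(cohort)",
                  sample_cohort(cfg$n_low, cfg$n_high, profiles,
                                seed = cfg$seed, rate = cfg$rate,
                                skel_rate = cfg$skel_rate))
  if (cfg$write_recordings) {
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
  }

  rows <- lapply(cohort, function(rec) {
    id <- rec$meta$subject_id
    iv <- stage("segment", id, segment_subtasks(rec$imu, control = control))
    fv <- stage("extract", id,
                extract_features(rec$imu, rec$skeleton, iv, rec$meta))
    cbind(data.frame(subject_id = id, label = rec$meta$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  features <- do.call(rbind, rows)
  write.csv(features, file.path(cfg$out_dir, "features.csv"), row.names = FALSE)

  tests <- stage("analyze", "(cohort)", compare_all_features(features))
  if (identical(cfg$stats$adjust, "BH")) {
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  }
  write.csv(tests, file.path(cfg$out_dir, "group_tests.csv"), row.names = FALSE)

  screened <- screen_large_effects(tests, cfg$stats$d_threshold,
                                   cfg$stats$alpha)
  write.csv(screened, file.path(cfg$out_dir, "screened.csv"), row.names = FALSE)

  uni <- do.call(rbind, lapply(screened$parameter, function(nm) {
    fit <- tryCatch(univariate_logistic(features[[nm]], features$label),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(parameter = nm, B = NA, SE = NA, OR = NA,
                        ci_low = NA, ci_high = NA, p_value = NA))
    }
    data.frame(parameter = nm, B = fit$coefficients[[2]], SE = fit$se[[2]],
               OR = fit$or[[2]], ci_low = fit$ci_low[[2]],
               ci_high = fit$ci_high[[2]], p_value = fit$p_values[[2]])
  }))
  if (is.null(uni)) {
    uni <- data.frame(parameter = character(0), B = numeric(0), SE = numeric(0),
                      OR = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_value = numeric(0))
  }
  write.csv(uni, file.path(cfg$out_dir, "univariate.csv"), row.names = FALSE)

  abl <- stage("analyze", "(cohort)", ablation(features))
  write.csv(as.data.frame(abl), file.path(cfg$out_dir, "ablation.csv"),
            row.names = FALSE)
  for (set_name in names(attr(abl, "fits"))) {
    rc <- roc_curve(attr(abl, "fits")[[set_name]]$fitted, features$label)
    write.csv(rc, file.path(cfg$out_dir, paste0("roc_", set_name, ".csv")),
              row.names = FALSE)
  }

  recovery <- recovery_report(features, profiles)
  write.csv(recovery, file.path(cfg$out_dir, "recovery.csv"), row.names = FALSE)

  manifest <- list(
    package = "tugfall",
    version = as.character(utils::packageVersion("tugfall")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  invisible(list(features = features, tests = tests, screened = screened,
                 univariate = uni, ablation = abl, recovery = recovery,
                 manifest = manifest))
}

#' Parameter-recovery summary
#'
#' Compares the recovered per-group means of the five profile-controlled
#' parameters (step length, step width, turn-to-sit peak yaw, walking knee
#' angle, turn pitch median) with the generating profile values, reporting
#' a z-score (recovered minus generating, over the standard error of the
#' recovered mean) and whether |z| <= 2.
#'
#' @param features cohort feature data frame.
#' @param profiles the generating profiles (list with `low`, `high`).
#' @return data frame: `parameter`, `group`, `generating`, `recovered`,
#'   `se`, `z`, `within_2se`.
#' @export
recovery_report <- function(features, profiles = default_profiles()) {
  map <- list(
    step_length = list(col = "keypoint_step_length_walk",
                       gen = function(p) p$step_length_mean_sd[1]),
    step_width = list(col = "keypoint_step_width_walk",
                      gen = function(p) p$step_width_mean_sd[1]),
    turn_to_sit_max_yaw = list(col = "gyr_max_yaw_turn_to_sit",
                               gen = function(p) p$turn_to_sit_max_yaw_mean_sd[1]),
    knee_angle_walk = list(col = "keypoint_right_knee_angle_walk",
                           gen = function(p) p$knee_angle_walk_mean_sd[1]),
    turn_pitch_median = list(col = "gyr_median_pitch_turn",
                             gen = function(p) p$pelvic_pitch_offset_turn)
  )
  rows <- list()
  for (nm in names(map)) {
    for (g in c("low", "high")) {
      x <- features[features$label == g, map[[nm]]$col]
      x <- x[is.finite(x)]
      gen <- map[[nm]]$gen(profiles[[g]])
      se <- if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
      z <- if (is.finite(se) && se > 0) (mean(x) - gen) / se else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, group = g, generating = gen,
        recovered = mean(x), se = se, z = z,
        within_2se = is.finite(z) && abs(z) <= 2
      )
    }
  }
  do.call(rbind, rows)
}
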