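# Independent brute-force oracles and shared fixtures.
# Oracles are deliberately naive (explicit loops) so they cannot share a
# code path with the implementation they check.

bf_summary_stats <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (v in x) {
    if (v > mx) mx <- v
    if (v < mn) mn <- v
  }
  s <- sort(x); n <- length(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  ssq <- 0
  for (v in x) ssq <- ssq + v^2
  m <- sum(x) / n
  dev <- 0
  for (v in x) dev <- dev + (v - m)^2
  list(max = mx, min = mn, median = med, range = mx - mn,
       rms = sqrt(ssq / n),
       cv = if (m == 0) NA_real_ else sqrt(dev / (n - 1)) / m)
}

bf_jerk <- function(x) {
  dmax <- -Inf; dsum <- 0
  for (i in seq_len(length(x) - 1)) {
    d <- abs(x[i + 1] - x[i])
    if (d > dmax) dmax <- d
    dsum <- dsum + d
  }
  list(max_jerk = dmax, mean_jerk = dsum / (length(x) - 1))
}

# Mann-Whitney U of x over y by pair enumeration, ties counted 1/2.
bf_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

bf_auc <- function(scores, labels) {
  hi <- scores[labels == "high"]; lo <- scores[labels == "low"]
  tot <- 0
  for (h in hi) for (l in lo) tot <- tot + (h > l) + 0.5 * (h == l)
  tot / (length(hi) * length(lo))
}

# Cached simulated trials so several test files can share one realization.
.trial_cache <- new.env(parent = emptyenv())
fixture_trial <- function(seed = 1, group = "low", rate = 5) {
  key <- paste(seed, group, rate)
  if (is.null(.trial_cache[[key]])) {
    .trial_cache[[key]] <- simulate_trial(default_profiles()[[group]],
                                          seed = seed, rate = rate)
  }
  .trial_cache[[key]]
}

truth_intervals <- function(truth) {
  subtask_intervals(
    truth$boundaries$sit_to_stand, truth$boundaries$walk_forward,
    truth$boundaries$turn, truth$boundaries$walk_back,
    truth$boundaries$turn_to_sit
  )
}

boundary_errors <- function(intervals, truth) {
  c(intervals$tug_start - truth$tug_start,
    intervals$walk_forward[1] - truth$boundaries$walk_forward[1],
    intervals$turn[1] - truth$boundaries$turn[1],
    intervals$turn[2] - truth$boundaries$turn[2],
    intervals$turn_to_sit[1] - truth$boundaries$turn_to_sit[1],
    intervals$tug_end - truth$tug_end)
}
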