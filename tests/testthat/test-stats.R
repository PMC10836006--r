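# Rebuild a sample with an exact mean and SD (n >= 2): two-point +/- spread
# around the mean, scaled to the target SD.
sample_with_moments <- function(mean, sd, n) {
  base <- rep(c(-1, 1), length.out = n)
  base <- base - mean(base)
  mean + base * sd / sd(base)
}

test_that("cohens_d reproduces printed effect sizes from group summaries", {
  # age row: 77.38 +/- 5.34 (n 26) vs 82.00 +/- 7.36 (n 15) -> 0.752
  expect_equal(cohens_d_summary(77.38, 5.34, 26, 82.00, 7.36, 15), 0.752,
               tolerance = 5e-4)
  expect_equal(
    cohens_d(sample_with_moments(77.38, 5.34, 26),
             sample_with_moments(82.00, 7.36, 15)),
    0.752, tolerance = 5e-4
  )
  # walking-assistance 0/1 coding: 4/22 yes/no vs 10/5 -> 1.236
  assist_lo <- rep(c(1, 0), c(4, 22))
  assist_hi <- rep(c(1, 0), c(10, 5))
  expect_equal(cohens_d(assist_lo, assist_hi), 1.236, tolerance = 5e-4)
  # turn-to-sit yaw RMS row -> 0.630
  expect_equal(cohens_d_summary(71.24, 24.6, 26, 57.22, 17.33, 15), 0.630,
               tolerance = 5e-4)

  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 7)), class = "tug_stats_error")
  expect_error(cohens_d(1, c(1, 2)), class = "tug_stats_error")
})

test_that("compare_groups gates on Shapiro-Wilk and routes binary to Fisher", {
  set.seed(1)  # draws for which both groups pass the Shapiro gate
  lab <- rep(c("low", "high"), c(60, 60))
  r_norm <- compare_groups(rnorm(120), lab)
  expect_identical(r_norm$test_used, "t")

  x <- c(rnorm(60), exp(rnorm(60, sd = 1.5)))  # one heavily skewed group
  r_skew <- compare_groups(x, lab)
  expect_identical(r_skew$test_used, "mann_whitney")

  r_bin <- compare_groups(rep(c(1, 0, 1, 0), c(4, 22, 10, 5)),
                          rep(c("low", "high"), c(26, 15)))
  expect_identical(r_bin$test_used, "fisher")
  expect_equal(r_bin$cohens_d, 1.236, tolerance = 5e-4)

  r_const <- compare_groups(rep(3.3, 120), lab)
  expect_true(r_const$degenerate)
  expect_true(is.na(r_const$p_value))

  expect_error(compare_groups(1:5, rep("low", 5)), class = "tug_stats_error")
})

test_that("Mann-Whitney U matches exhaustive pair enumeration", {
  set.seed(11)
  for (i in 1:30) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- sample(1:6, n1, replace = TRUE)  # discrete -> ties occur
    y <- sample(1:6, n2, replace = TRUE)
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$statistic)
    expect_equal(unname(w), bf_u_statistic(x, y))
  }
})

test_that("screening keeps p < 0.05 with d strictly above 0.8, sorted by p", {
  res <- data.frame(parameter = c("a", "b", "c"),
                    p_value = c(0.01, 0.02, 0.03),
                    cohens_d = c(0.79, 0.80, 0.81))
  out <- screen_large_effects(res)
  expect_identical(out$parameter, "c")

  expect_identical(nrow(screen_large_effects(res[0, ])), 0L)

  # the printed significant-parameter table: 17 rows, six with d > 0.8
  printed <- data.frame(
    parameter = c("cv_pitch_turn", "assistance", "max_yaw_tts", "cv_yaw_tts",
                  "step_length", "step_width", "median_pitch_turn",
                  "right_knee_walk", "rms_pitch_walk", "max_v_tts",
                  "mean_jerk_ap_tts", "pod_walk", "right_knee_turn", "age",
                  "mean_jerk_ml_sts", "rms_yaw_tts", "max_roll_tts"),
    p_value = c(0.0009, 0.001, 0.003, 0.005, 0.007, 0.008, 0.021, 0.022,
                0.026, 0.026, 0.029, 0.031, 0.034, 0.041, 0.049724,
                0.049724, 0.049724),
    cohens_d = c(0.745, 1.236, 0.957, 0.814, 0.909, 0.859, 0.786, 0.673,
                 0.692, 0.859, 0.641, 0.624, 0.666, 0.752, 0.456, 0.630,
                 0.698)
  )
  sel <- screen_large_effects(printed)
  expect_identical(nrow(sel), 6L)
  expect_equal(sort(sel$cohens_d, decreasing = TRUE),
               c(1.236, 0.957, 0.909, 0.859, 0.859, 0.814))
  expect_equal(sel$p_value, sort(sel$p_value))
})

test_that("univariate logistic reproduces the assistance odds ratio", {
  lab <- rep(c("low", "high"), c(26, 15))
  assist <- rep(c(1, 0, 1, 0), c(4, 22, 10, 5))
  fit <- univariate_logistic(assist, lab)
  expect_equal(unname(fit$or["x"]), 11.000, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["x"]), log(11), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), 2.398, tolerance = 1e-3)
  # Wald interval around OR
  expect_true(fit$ci_low[["x"]] < 11 && 11 < fit$ci_high[["x"]])

  # x with the same distribution in both classes: OR ~ 1, CI covers 1
  x_same <- rep(c(1, 2, 3, 4, 5), 8)
  lab2 <- rep(c("low", "high"), 20)
  fit2 <- univariate_logistic(x_same, lab2)
  expect_equal(unname(fit2$or["x"]), 1, tolerance = 1e-6)
  expect_true(fit2$ci_low[["x"]] < 1 && 1 < fit2$ci_high[["x"]])

  # complete separation is refused
  expect_error(univariate_logistic(c(1:10, 21:30), rep(c("low", "high"), each = 10)),
               "separation", class = "tug_separation_error")
  expect_error(univariate_logistic(rep(1, 10), rep(c("low", "high"), 5)),
               class = "tug_separation_error")
  expect_error(univariate_logistic(1:5, rep("high", 5)), class = "tug_stats_error")
})

test_that("multivariate logistic agrees with univariate on one feature", {
  set.seed(12)
  x <- rnorm(60)
  lab <- ifelse(runif(60) < plogis(0.5 + x), "high", "low")
  if (length(unique(lab)) < 2) lab[1:2] <- c("low", "high")
  uni <- univariate_logistic(x, lab)
  multi <- multivariate_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                                 lab)
  expect_equal(unname(multi$coefficients), unname(uni$coefficients),
               tolerance = 1e-8)
  expect_equal(multi$fitted, uni$fitted, tolerance = 1e-8)

  X <- cbind(a = x, b = x)  # duplicated column
  expect_error(multivariate_logistic(X, lab), class = "tug_collinearity_error")
  expect_error(multivariate_logistic(matrix(rnorm(8), 2, 4),
                                     c("low", "high")),
               class = "tug_stats_error")
})

test_that("label-independent predictors yield calibrated Wald tests", {
  set.seed(13)
  hits <- 0; total <- 0
  for (i in 1:40) {
    X <- matrix(rnorm(200 * 3), 200, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    lab <- rep(c("low", "high"), 100)
    fit <- multivariate_logistic(X, lab)
    p <- fit$p_values[-1]
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_lt(hits / total, 0.12)  # ~5% nominal
  expect_gt(hits / total, 0.005)
})

test_that("AUC matches the brute-force pairwise probability and the U identity", {
  lab <- rep(c("low", "high"), c(6, 5))
  expect_equal(roc_auc(c(1:6, 11:15), lab), 1)
  expect_equal(roc_auc(rep(2, 11), lab), 0.5)
  expect_error(roc_auc(1:5, rep("low", 5)), class = "tug_stats_error")

  set.seed(14)
  for (i in 1:30) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    scores <- c(sample(1:8, n1, TRUE), sample(1:8, n2, TRUE))
    labels <- rep(c("low", "high"), c(n1, n2))
    a <- roc_auc(scores, labels)
    expect_equal(a, bf_auc(scores, labels))
    # AUC = U / (n1 n2) with U the Mann-Whitney statistic of high over low
    u <- bf_u_statistic(scores[labels == "high"], scores[labels == "low"])
    expect_equal(a, u / (n1 * n2))
  }
})

test_that("roc_curve spans (0,0) to (1,1) monotonically", {
  set.seed(15)
  scores <- rnorm(30)
  lab <- rep(c("low", "high"), 15)
  rc <- roc_curve(scores, lab)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("ablation fits the three published feature sets", {
  feats <- cohort_features(sample_cohort(14, 10, seed = 33))
  abl <- ablation(feats)
  expect_identical(abl$feature_set, c("IMU", "DepthCamera", "Combined"))
  expect_true(all(abl$auc >= 0 & abl$auc <= 1))
  expect_identical(abl$n_features, c(3L, 2L, 5L))

  # identical feature sets give identical AUCs
  same <- ablation(feats, feature_sets = list(
    A = c("keypoint_step_length_walk", "keypoint_step_width_walk"),
    B = c("keypoint_step_width_walk", "keypoint_step_length_walk")
  ))
  expect_equal(same$auc[1], same$auc[2])

  bad <- feats[, setdiff(names(feats), "keypoint_step_width_walk")]
  expect_error(ablation(bad, labels = feats$label), "step_width",
               class = "tug_stats_error")
})
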