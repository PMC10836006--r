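# Two-group discrimination statistics: normality-gated tests, Cohen's d
# screening, logistic regression and the sensor-ablation AUC comparison.

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' d = |mean1 - mean2| / s_pooled with the (n-1)-weighted pooled SD
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). Reported
#' as a non-negative magnitude. Binary variables are expected coded 0/1.
#'
#' @param sample_low,sample_high numeric vectors (each length >= 2).
#' @return scalar d >= 0.
#' @examples
#' # from printed summaries: rebuild two-point samples with exact mean/SD
#' cohens_d(c(1, 2, 3), c(2, 3, 4))
#' @export
cohens_d <- function(sample_low, sample_high) {
  n1 <- length(sample_low); n2 <- length(sample_high)
  if (n1 < 2L || n2 < 2L) {
    tug_stop("tug_stats_error", "cohens_d needs >= 2 observations per group")
  }
  sp2 <- ((n1 - 1) * var(sample_low) + (n2 - 1) * var(sample_high)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) tug_stop("tug_stats_error", "zero pooled SD")
  abs(mean(sample_low) - mean(sample_high)) / sqrt(sp2)
}

#' Cohen's d from printed group summaries
#'
#' Convenience form of [cohens_d()] for published mean / SD / n summaries.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return scalar d >= 0.
#' @examples
#' cohens_d_summary(77.38, 5.34, 26, 82.00, 7.36, 15)  # 0.752
#' @export
cohens_d_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) tug_stop("tug_stats_error", "zero pooled SD")
  abs(mean1 - mean2) / sqrt(sp2)
}

is_binary <- function(x) all(x %in% c(0, 1))

#' Normality-gated two-group comparison
#'
#' For a continuous feature, a Shapiro-Wilk test is run within each group
#' at alpha = 0.05; if both groups pass, a two-sided pooled-variance
#' (Student) t-test is used, otherwise a two-sided Mann-Whitney U test with
#' tie correction. Binary (0/1) features are tested with Fisher's exact
#' test. Cohen's d is attached in all cases (binary features via their 0/1
#' coding).
#'
#' @param values numeric feature values for all subjects.
#' @param labels group labels, coercible to two levels with `"low"` /
#'   `"high"` semantics (a factor/character containing "low" and "high",
#'   or a 0/1 vector where 1 = high risk).
#' @param parameter optional feature name carried into the result.
#' @param alpha gate level for the Shapiro-Wilk test.
#' @return a `tug_group_test` list: `parameter`, per-group `n`, `mean`,
#'   `sd`, `test_used` (`"t"`, `"mann_whitney"` or `"fisher"`), `p_value`,
#'   `cohens_d`, `degenerate`.
#' @export
compare_groups <- function(values, labels, parameter = NA_character_,
                           alpha = 0.05) {
  g <- normalize_labels(labels)
  x_lo <- values[g == "low"]
  x_hi <- values[g == "high"]
  if (!length(x_lo) || !length(x_hi)) {
    tug_stop("tug_stats_error", "both groups must be non-empty")
  }
  res <- list(parameter = parameter,
              n = c(low = length(x_lo), high = length(x_hi)),
              mean = c(low = mean(x_lo), high = mean(x_hi)),
              sd = c(low = sd(x_lo), high = sd(x_hi)),
              test_used = NA_character_, p_value = NA_real_,
              cohens_d = NA_real_, degenerate = FALSE)
  if (sd(values) == 0 || (sd(x_lo) == 0 && sd(x_hi) == 0)) {
    res$degenerate <- TRUE
    class(res) <- "tug_group_test"
    return(res)
  }
  if (is_binary(values)) {
    tab <- table(factor(values, levels = c(0, 1)), g)
    res$test_used <- "fisher"
    res$p_value <- fisher.test(tab)$p.value
  } else {
    normal <- function(x) {
      if (length(x) < 3L || sd(x) == 0) return(FALSE)
      shapiro.test(x)$p.value > alpha
    }
    if (normal(x_lo) && normal(x_hi)) {
      res$test_used <- "t"
      res$p_value <- t.test(x_lo, x_hi, var.equal = TRUE)$p.value
    } else {
      res$test_used <- "mann_whitney"
      res$p_value <- suppressWarnings(
        wilcox.test(x_lo, x_hi, exact = FALSE, correct = TRUE)$p.value
      )
    }
  }
  res$cohens_d <- cohens_d(x_lo, x_hi)
  class(res) <- "tug_group_test"
  res
}

normalize_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    return(factor(ifelse(labels == 1, "high", "low"), levels = c("low", "high")))
  }
  l <- as.character(labels)
  if (!all(l %in% c("low", "high"))) {
    tug_stop("tug_stats_error", "labels must be 'low'/'high' or 0/1")
  }
  factor(l, levels = c("low", "high"))
}

#' Compare every feature of a cohort feature table
#'
#' @param features data frame from [cohort_features()] (or any data frame
#'   with a `label` column plus numeric feature columns).
#' @param exclude columns to skip (default id/label bookkeeping).
#' @return data frame with one row per feature: group summaries,
#'   `test_used`, `p_value`, `cohens_d`, `degenerate`.
#' @export
compare_all_features <- function(features,
                                 exclude = c("subject_id", "label")) {
  labels <- features$label
  cols <- setdiff(names(features), exclude)
  rows <- lapply(cols, function(nm) {
    x <- features[[nm]]
    if (!is.numeric(x) || anyNA(x)) {
      return(data.frame(parameter = nm, n_low = NA, n_high = NA,
                        mean_low = NA, mean_high = NA, sd_low = NA,
                        sd_high = NA, test_used = NA, p_value = NA,
                        cohens_d = NA, degenerate = NA))
    }
    r <- compare_groups(x, labels, parameter = nm)
    data.frame(parameter = nm, n_low = r$n[["low"]], n_high = r$n[["high"]],
               mean_low = r$mean[["low"]], mean_high = r$mean[["high"]],
               sd_low = r$sd[["low"]], sd_high = r$sd[["high"]],
               test_used = r$test_used, p_value = r$p_value,
               cohens_d = r$cohens_d, degenerate = r$degenerate)
  })
  do.call(rbind, rows)
}

#' Screen for significant large-effect parameters
#'
#' Keeps parameters with p < `alpha` and Cohen's d strictly greater than
#' `threshold` (large effect), sorted by ascending p-value.
#'
#' @param results data frame from [compare_all_features()] (needs columns
#'   `parameter`, `p_value`, `cohens_d`).
#' @param threshold effect-size cutoff (default 0.8).
#' @param alpha significance cutoff (default 0.05).
#' @return the selected rows, ordered by `p_value`.
#' @export
screen_large_effects <- function(results, threshold = 0.8, alpha = 0.05) {
  if (is.null(results) || !nrow(results)) return(results[0, , drop = FALSE])
  keep <- !is.na(results$p_value) & !is.na(results$cohens_d) &
    results$p_value < alpha & results$cohens_d > threshold
  out <- results[keep, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

logistic_from_glm <- function(fit, conf_z = qnorm(0.975)) {
  sm <- summary(fit)$coefficients
  b <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  structure(list(
    coefficients = b,
    se = se,
    or = exp(b),
    ci_low = exp(b - conf_z * se),
    ci_high = exp(b + conf_z * se),
    p_values = sm[, "Pr(>|z|)"],
    fitted = as.numeric(predict(fit, type = "response")),
    converged = fit$converged
  ), class = "tug_logit")
}

# Complete separation drives the in-sample deviance to 0 (fitted
# probabilities to 0/1); coefficient magnitude is no criterion because
# meter-scaled gait predictors legitimately carry slopes of ~30.
check_separation <- function(fit) {
  if (anyNA(coef(fit))) {
    tug_stop("tug_separation_error", "non-identifiable (degenerate predictor)")
  }
  if (!fit$converged || fit$deviance < 1e-6) {
    tug_stop("tug_separation_error", "non-identifiable (separation)")
  }
}

#' Univariate logistic regression of fall-risk group on one parameter
#'
#' Maximum-likelihood fit of P(high risk) = logistic(B0 + B x). The odds
#' ratio is exp(B) with a Wald 95% CI exp(B +/- 1.96 SE). For a binary 0/1
#' predictor the fitted OR equals the sample cross-product ratio.
#'
#' @param x numeric predictor.
#' @param labels group labels (see [compare_groups()]).
#' @return a `tug_logit` list: `coefficients`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p_values`, `fitted` (in-sample probabilities of high
#'   risk).
#' @examples
#' lab <- rep(c("low", "high"), c(26, 15))
#' assist <- c(rep(1, 4), rep(0, 22), rep(1, 10), rep(0, 5))
#' fit <- univariate_logistic(assist, lab)
#' fit$or[["x"]]  # 11.000
#' @export
univariate_logistic <- function(x, labels) {
  g <- normalize_labels(labels)
  if (nlevels(droplevels(g)) < 2L) {
    tug_stop("tug_stats_error", "both classes must be present")
  }
  if (any(!is.finite(x))) tug_stop("tug_stats_error", "predictor must be finite")
  y <- as.integer(g == "high")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  check_separation(fit)
  logistic_from_glm(fit)
}

#' Multivariate logistic regression
#'
#' Joint MLE fit of the group label on a feature matrix; in-sample
#' predicted probabilities are retained for ROC analysis. Exact
#' collinearity and complete separation raise explicit errors.
#'
#' @param X numeric matrix or data frame of predictors (n x p, p < n).
#' @param labels group labels (see [compare_groups()]).
#' @return a `tug_logit` (see [univariate_logistic()]).
#' @export
multivariate_logistic <- function(X, labels) {
  X <- as.matrix(X)
  g <- normalize_labels(labels)
  if (nlevels(droplevels(g)) < 2L) {
    tug_stop("tug_stats_error", "both classes must be present")
  }
  if (any(!is.finite(X))) tug_stop("tug_stats_error", "predictors must be finite")
  if (nrow(X) <= ncol(X)) {
    tug_stop("tug_stats_error", "need more observations than predictors")
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    tug_stop("tug_collinearity_error", "collinear predictors")
  }
  y <- as.integer(g == "high")
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = df))
  check_separation(fit)
  logistic_from_glm(fit)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a randomly
#' chosen high-risk score exceeds a randomly chosen low-risk score, ties
#' counted 1/2. Identical to U / (n1 n2).
#'
#' @param scores numeric risk scores (higher = more high-risk).
#' @param labels group labels (see [compare_groups()]).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  g <- normalize_labels(labels)
  n_hi <- sum(g == "high"); n_lo <- sum(g == "low")
  if (n_hi == 0L || n_lo == 0L) {
    tug_stop("tug_stats_error", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[g == "high"]) - n_hi * (n_hi + 1) / 2) / (n_hi * n_lo)
}

#' ROC curve coordinates
#'
#' @param scores,labels as in [roc_auc()].
#' @return data frame with `threshold`, `fpr`, `tpr` (one row per distinct
#'   score plus the endpoints).
#' @export
roc_curve <- function(scores, labels) {
  g <- normalize_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(cut) {
    pred <- scores >= cut
    data.frame(threshold = cut,
               fpr = sum(pred & g == "low") / sum(g == "low"),
               tpr = sum(pred & g == "high") / sum(g == "high"))
  }))
}

# The published ablation feature sets.
ablation_sets <- function() list(
  IMU = c("gyr_max_yaw_turn_to_sit", "gyr_cv_yaw_turn_to_sit",
          "acc_max_V_turn_to_sit"),
  DepthCamera = c("keypoint_step_length_walk", "keypoint_step_width_walk"),
  Combined = c("gyr_max_yaw_turn_to_sit", "gyr_cv_yaw_turn_to_sit",
               "acc_max_V_turn_to_sit", "keypoint_step_length_walk",
               "keypoint_step_width_walk")
)

#' Sensor-ablation experiment
#'
#' Fits three multivariate logistic models — IMU-only features (turn-to-sit
#' peak yaw, turn-to-sit yaw CV, turn-to-sit peak vertical acceleration),
#' depth-camera-only features (step length, step width), and their
#' combination — and reports the in-sample AUC of each, quantifying the
#' complementarity of the two sensors.
#'
#' @param features cohort feature data frame (needs the five named feature
#'   columns and `label`).
#' @param labels optional labels (default `features$label`).
#' @param feature_sets named list of feature-name vectors (default: the
#'   published three sets).
#' @return data frame of class `tug_ablation`: `feature_set`, `n_features`,
#'   `auc`, plus the fits in `attr(, "fits")`.
#' @export
ablation <- function(features, labels = features$label,
                     feature_sets = ablation_sets()) {
  for (set_name in names(feature_sets)) {
    miss <- setdiff(feature_sets[[set_name]], names(features))
    if (length(miss)) {
      tug_stop("tug_stats_error", "missing named feature(s): %s",
               paste(miss, collapse = ", "))
    }
  }
  fits <- list()
  rows <- lapply(names(feature_sets), function(set_name) {
    cols <- feature_sets[[set_name]]
    fit <- multivariate_logistic(features[, cols, drop = FALSE], labels)
    fits[[set_name]] <<- fit
    data.frame(feature_set = set_name, n_features = length(cols),
               auc = roc_auc(fit$fitted, labels))
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("tug_ablation", class(out))
  out
}

#' @export
print.tug_group_test <- function(x, ...) {
  cat(sprintf("<tug_group_test> %s: %s test, p = %.4g, d = %.3f\n",
              x$parameter, x$test_used, x$p_value, x$cohens_d))
  invisible(x)
}

#' @export
print.tug_logit <- function(x, ...) {
  cat("<tug_logit>\n")
  print(data.frame(B = x$coefficients, SE = x$se, OR = x$or,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_values))
  invisible(x)
}
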