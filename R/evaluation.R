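#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic with
#' midrank handling of ties: the probability that a randomly chosen presence
#' is scored above a randomly chosen absence (ties counting one half).
#' Equals trapezoidal integration of the ROC curve.
#'
#' @param scores numeric prediction per row.
#' @param labels binary labels (both classes required).
#' @param weights optional positive per-row weights; the weighted AUC sums
#'   `w_i * w_j` over presence/absence pairs.
#' @return scalar in \[0, 1\].
#' @export
auc <- function(scores, labels, weights = NULL) {
  if (length(scores) != length(labels)) stop_bad_arg("length mismatch")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_bad_arg("AUC needs both classes present")
  if (is.null(weights)) {
    r <- rank(scores)   # midranks
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    sp <- scores[pos]; sa <- scores[!pos]
    wp <- weights[pos]; wa <- weights[!pos]
    cmp <- outer(sp, sa, function(a, b) (a > b) + 0.5 * (a == b))
    sum(outer(wp, wa) * cmp) / (sum(wp) * sum(wa))
  }
}

#' Weighted Bernoulli deviance
#'
#' `-2 * sum(w * (y*log(p) + (1-y)*log(1-p)))`, normalized either by the
#' total weight (`average = "weight"`, the default: a weighted mean of the
#' per-row deviance, invariant to rescaling all weights) or by the row count
#' (`average = "obs"`, the convention of the classical BRT cross-validation
#' toolchain, used for all reported CV deviances in this package).
#' Predictions are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param weights positive weights (default 1).
#' @param average `"weight"` or `"obs"`.
#' @return non-negative scalar.
#' @export
weighted_deviance <- function(scores, labels, weights = NULL,
                              average = c("weight", "obs")) {
  average <- match.arg(average)
  if (length(scores) != length(labels))
    stop_bad_arg("`scores` and `labels` lengths differ")
  if (is.null(weights)) weights <- rep(1, length(labels))
  if (length(weights) != length(labels))
    stop_bad_arg("`weights` length differs from `labels`")
  p <- clamp01(scores)
  ll <- weights * (labels * log(p) + (1 - labels) * log(1 - p))
  denom <- if (average == "weight") sum(weights) else length(labels)
  -2 * sum(ll) / denom
}

#' True-skill-statistic profile over a threshold sweep
#'
#' Sweeps thresholds 0.00, 0.01, ..., 1.00; at threshold t a row is
#' predicted present iff `score >= t`. Sensitivity and specificity come from
#' the confusion matrix and `TSS = sensitivity + specificity - 1`. Two
#' thresholds are selected: the one maximizing TSS (ties resolved to the
#' lowest threshold) and the 10th percentile (linear interpolation) of the
#' presence-row scores, each reported with its TSS.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels (both classes required).
#' @return object of class `tss_profile`: data.frame `profile`
#'   (`threshold`, `sensitivity`, `specificity`, `tss`) plus `t_max_tss`,
#'   `max_tss`, `t_p10`, `tss_p10`.
#' @export
tss_profile <- function(scores, labels) {
  pos <- labels == 1
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop_bad_arg("TSS needs both classes present")
  thr <- seq(0, 1, by = 0.01)
  sens_spec <- function(t) {
    pred <- scores >= t
    c(sens = sum(pred & pos) / sum(pos),
      spec = sum(!pred & !pos) / sum(!pos))
  }
  ss <- vapply(thr, sens_spec, numeric(2))
  prof <- data.frame(threshold = thr, sensitivity = ss["sens", ],
                     specificity = ss["spec", ],
                     tss = ss["sens", ] + ss["spec", ] - 1)
  i_max <- which.max(prof$tss)          # first max = lowest threshold
  p10 <- as.numeric(stats::quantile(scores[pos], 0.10, type = 7))
  ss10 <- sens_spec(p10)
  structure(list(profile = prof,
                 t_max_tss = prof$threshold[i_max],
                 max_tss = prof$tss[i_max],
                 t_p10 = p10,
                 tss_p10 = as.numeric(ss10["sens"] + ss10["spec"] - 1)),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("<tss_profile> max TSS %.4f at threshold %.2f; TSS %.4f at 10th-percentile threshold %.5f\n",
              x$max_tss, x$t_max_tss, x$tss_p10, x$t_p10))
  invisible(x)
}

#' Compare two metric samples with the normality/homoscedasticity cascade
#'
#' Runs Shapiro-Wilk on each sample and Levene's test (centred on the mean)
#' across the pair. When every p-value exceeds 0.05, the samples are
#' compared with a two-tailed pooled-variance t-test; otherwise with a
#' two-sided Wilcoxon-Mann-Whitney test. Significance is judged at `alpha`.
#'
#' @param sample_a,sample_b numeric metric samples (each >= 3 values).
#' @param alpha significance level (default 0.05).
#' @return object of class `comparison_report`: the per-sample Shapiro
#'   p-values, Levene p-value, the test used (`"t_test"` or
#'   `"wilcoxon_mann_whitney"`), its statistic and p-value, and the
#'   `significant` flag.
#' @export
compare_metric_samples <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop_bad_arg("each sample needs at least 3 values")
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: not plausibly normal
    stats::shapiro.test(x)$p.value
  }
  norm_p <- c(a = shapiro_p(sample_a), b = shapiro_p(sample_b))
  lev <- car::leveneTest(
    c(sample_a, sample_b),
    factor(rep(c("a", "b"), c(length(sample_a), length(sample_b)))),
    center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  parametric <- all(norm_p > 0.05) && levene_p > 0.05
  if (parametric) {
    tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    test_used <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b))
    test_used <- "wilcoxon_mann_whitney"
    statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(normality_p = norm_p, levene_p = levene_p,
                 test_used = test_used, statistic = statistic, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: statistic = %.4f, p = %.4g (%ssignificant at %.2f)\n",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Assemble cross-validated metric samples for one species and scheme
#'
#' For the target-group schemes the samples are the per-fold AUC and
#' deviance values of the final stepwise-selected model (n = number of
#' folds); for the random scheme they are the per-replicate mean
#' cross-validated AUC and deviance (n = number of replicates).
#'
#' @param fits a single `brt_model` from [gbm_step_fit()] (UTGB/WTGB) or a
#'   list of replicate models (RDM).
#' @param scheme `"UTGB"`, `"WTGB"` or `"RDM"`.
#' @param species species label carried into the result.
#' @return object of class `cv_metrics` with `per_fold_auc`,
#'   `per_fold_deviance` (the comparison samples), their means and standard
#'   errors (`SE = sd / sqrt(n)`), and for RDM the per-replicate means.
#' @export
collect_cv_metrics <- function(fits, scheme = c("UTGB", "WTGB", "RDM"),
                               species = "species") {
  scheme <- match.arg(scheme)
  get_cv <- function(m) {
    cv <- m$training_summary$cv
    if (is.null(cv)) stop_bad_arg("model lacks cross-validation results; ",
                                  "fit it with gbm_step_fit()")
    cv
  }
  if (scheme == "RDM") {
    if (!is.list(fits) || inherits(fits, "brt_model") || length(fits) < 2)
      stop_bad_arg("RDM expects a list of >= 2 replicate models")
    auc_s <- vapply(fits, function(m) mean(get_cv(m)$per_fold_auc), numeric(1))
    dev_s <- vapply(fits, function(m) mean(get_cv(m)$per_fold_deviance),
                    numeric(1))
  } else {
    if (!inherits(fits, "brt_model"))
      stop_bad_arg(scheme, " expects a single brt_model")
    cv <- get_cv(fits)
    auc_s <- cv$per_fold_auc
    dev_s <- cv$per_fold_deviance
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(scheme = scheme, species = species,
                 per_fold_auc = auc_s, per_fold_deviance = dev_s,
                 mean_auc = mean(auc_s), se_auc = se(auc_s),
                 mean_deviance = mean(dev_s), se_deviance = se(dev_s),
                 n = length(auc_s)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> %s / %s (n = %d): AUC %.3f +/- %.3f, deviance %.3f +/- %.3f\n",
              x$species, x$scheme, x$n, x$mean_auc, x$se_auc,
              x$mean_deviance, x$se_deviance))
  invisible(x)
}
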