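test_that("rank-based AUC matches exhaustive pair counting and ROC integration", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # 3 of 4 presence/absence pairs concordant
  expect_equal(auc(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:3 / 4, c(1, 1, 1)), "both classes")

  set.seed(50)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(auc(s, y), auc_trapezoid(s, y), tolerance = 1e-12)
    # weighted AUC with unit weights agrees with the rank form
    expect_equal(auc(s, y, weights = rep(2, n)), auc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("weighted deviance has the stated closed forms and normalizations", {
  y <- rep(c(1, 0), 10)
  expect_equal(weighted_deviance(rep(0.5, 20), y), 2 * log(2),
               tolerance = 1e-12)
  expect_lt(weighted_deviance(y, y), 1e-10)   # perfect fit, clamped

  set.seed(51)
  p <- runif(20); w <- runif(20, 0.1, 4)
  # per-unit-weight form is invariant to rescaling all weights
  expect_equal(weighted_deviance(p, y, w), weighted_deviance(p, y, 2 * w),
               tolerance = 1e-12)
  # per-observation form scales with the weights (the CV reporting form)
  expect_equal(weighted_deviance(p, y, 2 * w, average = "obs"),
               2 * weighted_deviance(p, y, w, average = "obs"),
               tolerance = 1e-12)
  expect_equal(weighted_deviance(p, y, w, average = "obs"),
               weighted_deviance(p, y, w) * sum(w) / 20, tolerance = 1e-12)
  expect_error(weighted_deviance(p[1:3], y), "lengths differ")
})

test_that("TSS profiles match brute-force confusion matrices at all 101 thresholds", {
  # the worked 6-point set
  s <- c(0.9, 0.6, 0.4, 0.7, 0.3, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  pr <- tss_profile(s, y)
  for (i in seq_len(101)) {
    t <- pr$profile$threshold[i]
    expect_equal(pr$profile$tss[i], oracle_tss_at(s, y, t), tolerance = 1e-12)
  }
  expect_equal(pr$profile$tss,
               pr$profile$sensitivity + pr$profile$specificity - 1,
               tolerance = 1e-12)
  # t = 0 predicts everything present
  expect_equal(pr$profile$sensitivity[1], 1)
  expect_equal(pr$profile$specificity[1], 0)
  expect_equal(pr$profile$tss[1], 0)

  # perfect scores: max TSS 1, attained at the lowest qualifying threshold
  perfect <- tss_profile(c(1, 1, 1, 0, 0, 0), y)
  expect_equal(perfect$max_tss, 1)
  expect_equal(oracle_tss_at(c(1, 1, 1, 0, 0, 0), y, 0.5), 1)

  # random profiles: identity + threshold relations
  set.seed(52)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    yy <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2) next
    ss <- runif(n)
    p2 <- tss_profile(ss, yy)
    expect_equal(p2$profile$tss,
                 p2$profile$sensitivity + p2$profile$specificity - 1,
                 tolerance = 1e-12)
    expect_true(all(diff(p2$profile$sensitivity) <= 0))
    expect_gte(p2$max_tss + 1e-12, p2$tss_p10)
    expect_equal(p2$t_p10,
                 as.numeric(quantile(ss[yy == 1], 0.1)), tolerance = 1e-12)
  }
})

test_that("the comparison cascade routes to the right test", {
  set.seed(53)
  a <- rnorm(10); b <- rnorm(10)
  cr <- compare_metric_samples(a, b)
  expect_equal(cr$test_used, "t_test")
  expect_equal(cr$p_value, t.test(a, b, var.equal = TRUE)$p.value)

  skewed <- rexp(10)^3
  cr2 <- compare_metric_samples(skewed, rnorm(10))
  expect_equal(cr2$test_used, "wilcoxon_mann_whitney")

  # heteroscedastic pair (equal means, very unequal spread) -> Levene fails
  set.seed(54)
  a3 <- rnorm(12, sd = 0.01); b3 <- rnorm(12, sd = 10)
  cr3 <- compare_metric_samples(a3, b3)
  expect_lt(cr3$levene_p, 0.05)
  expect_equal(cr3$test_used, "wilcoxon_mann_whitney")

  expect_error(compare_metric_samples(1:2, 1:5), "at least 3")
})

test_that("under a Gaussian null the cascade keeps its nominal size", {
  set.seed(55)
  hits <- 0L
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    if (compare_metric_samples(rnorm(10), rnorm(10))$significant)
      hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.03)
  expect_lt(hits / n_sim, 0.07)
})

test_that("cv metric assembly mirrors the fold/replicate sampling design", {
  d <- make_logit_data(56, n = 60, p = 3)
  p <- brt_params(learning_rate = 0.1, tree_complexity = 2, bag_fraction = 1,
                  min_obs = 3, n_folds = 5, step_size = 10, max_trees = 50,
                  patience = 2, seed = 2)
  m <- suppressWarnings(gbm_step_fit(d$X, d$y, params = p))
  cm <- collect_cv_metrics(m, "UTGB", "sp")
  expect_equal(cm$n, 5)
  expect_equal(cm$mean_auc, mean(m$training_summary$cv$per_fold_auc))
  expect_equal(cm$se_auc,
               sd(m$training_summary$cv$per_fold_auc) / sqrt(5))

  ms <- lapply(1:4, function(i) {
    p$seed <- i
    suppressWarnings(gbm_step_fit(d$X, d$y, params = p))
  })
  cr <- collect_cv_metrics(ms, "RDM", "sp")
  expect_equal(cr$n, 4)
  expect_equal(cr$per_fold_auc,
               vapply(ms, function(m) mean(m$training_summary$cv$per_fold_auc),
                      numeric(1)))
  expect_error(collect_cv_metrics(ms[[1]], "RDM", "sp"), "replicate models")
  expect_error(collect_cv_metrics(ms, "UTGB", "sp"), "single brt_model")
  plain <- fit_boosted_trees(d$X, d$y, params = p, n_trees = 10)
  expect_error(collect_cv_metrics(plain, "UTGB", "sp"), "cross-validation")
})
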