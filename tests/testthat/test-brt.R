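deep_params <- function(...) brt_params(learning_rate = 0.2,
                                        tree_complexity = 2,
                                        bag_fraction = 1, min_obs = 2,
                                        n_folds = 3, step_size = 10,
                                        max_trees = 100, seed = 1, ...)

test_that("boosting matches the brute-force oracle with full bagging", {
  # depth-1, 3 trees, 8 points — the minimal worked case
  set.seed(21)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("V1", "V2")))
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  p1 <- brt_params(learning_rate = 0.1, tree_complexity = 1, bag_fraction = 1,
                   min_obs = 1, seed = 1)
  m <- fit_boosted_trees(X, y, params = p1, n_trees = 3)
  expect_lt(max(abs(predict(m) -
                      oracle_boost(X, y, NULL, 0.1, 1, 1, 3))), 1e-9)

  # deeper trees, weights, 50 rows
  d <- make_logit_data(22, n = 50, p = 4)
  set.seed(1); w <- runif(50, 0.5, 2)
  p2 <- brt_params(learning_rate = 0.1, tree_complexity = 3, bag_fraction = 1,
                   min_obs = 3, seed = 1)
  m2 <- fit_boosted_trees(d$X, d$y, w, params = p2, n_trees = 25)
  expect_lt(max(abs(predict(m2) -
                      oracle_boost(d$X, d$y, w, 0.1, 3, 3, 25))), 1e-9)
})

test_that("weight rescaling, label flips and row order leave predictions invariant", {
  d <- make_logit_data(30, n = 40)
  w <- runif(40, 0.2, 3)
  p <- deep_params()
  m1 <- fit_boosted_trees(d$X, d$y, w, p, n_trees = 40)
  m2 <- fit_boosted_trees(d$X, d$y, w * 7.3, p, n_trees = 40)
  expect_lt(max(abs(predict(m1) - predict(m2))), 1e-10)

  mflip <- fit_boosted_trees(d$X, 1 - d$y, w, p, n_trees = 40)
  expect_lt(max(abs(predict(m1) - (1 - predict(mflip)))), 1e-9)

  perm <- sample(40)
  expect_equal(predict(m1, d$X[perm, ]), predict(m1)[perm], tolerance = 1e-14)
})

test_that("training deviance decreases and saturates on separable data", {
  d <- make_logit_data(31, n = 40, beta = c(5, 0, 0, 0))
  m <- fit_boosted_trees(d$X, d$y, params = deep_params(), n_trees = 200)
  tr <- m$training_summary$train_deviance
  expect_lt(tr[200], tr[1])
  expect_true(all(diff(tr) <= 1e-12))      # non-increasing with bag = 1
  expect_lt(weighted_deviance(predict(m), d$y), 0.05)
})

test_that("prediction contracts: empty ensemble, truncation, missing columns", {
  d <- make_logit_data(32, n = 30)
  m <- fit_boosted_trees(d$X, d$y, params = deep_params(), n_trees = 10)
  expect_equal(predict(m, n_trees = 0),
               rep(plogis(m$intercept), 30))
  expect_error(predict(m, n_trees = 11), "exceeds")
  expect_error(predict(m, d$X[, 1:2]), "lacks predictor")
  expect_true(all(predict(m) > 0 & predict(m) < 1))
  expect_error(fit_boosted_trees(d$X, rep(1, 30), params = deep_params(),
                                 n_trees = 5), "single class")
  expect_error(fit_boosted_trees(d$X, d$y, w = rep(-1, 30),
                                 params = deep_params(), n_trees = 5),
               "positive")
})

test_that("stepwise CV selection agrees with an exhaustive candidate scan", {
  d <- make_logit_data(33, n = 60, p = 3, beta = c(1.5, -1, 0))
  p <- brt_params(learning_rate = 0.05, tree_complexity = 2,
                  bag_fraction = 1, min_obs = 5, n_folds = 5, step_size = 10,
                  max_trees = 150, patience = 100, seed = 4)
  m <- suppressWarnings(gbm_step_fit(d$X, d$y, params = p))
  cv <- m$training_summary$cv

  # oracle: recompute the mean held-out deviance at every candidate count
  # from the retained fold models via predict(), then take the argmin
  cand <- cv$trace$n_trees
  dev_at <- vapply(cand, function(nt) {
    mean(vapply(cv$fold_models, function(fm) {
      f <- fm$intercept +
        tgbsdm:::cpp_predict_trees(fm$trees, d$X[fm$ho, , drop = FALSE],
                                   as.integer(nt))
      tgbsdm:::holdout_deviance(plogis(f), d$y[fm$ho], rep(1, length(fm$ho)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cv$trace$mean_cv_deviance, dev_at, tolerance = 1e-10)
  expect_equal(m$n_trees_used, cand[which.min(dev_at)])

  # determinism: same seed, same folds and selection
  m2 <- suppressWarnings(gbm_step_fit(d$X, d$y, params = p))
  expect_identical(m$training_summary$cv$fold, m2$training_summary$cv$fold)
  expect_identical(m$n_trees_used, m2$n_trees_used)
  expect_equal(predict(m), predict(m2), tolerance = 1e-14)
})

test_that("stepwise fit warns below 1000 trees and errors on infeasible folds", {
  d <- make_logit_data(34, n = 40)
  p <- deep_params()
  expect_warning(gbm_step_fit(d$X, d$y, params = p), "< 1000")
  p$n_folds <- 30L
  expect_error(suppressWarnings(gbm_step_fit(d$X, d$y, params = p)),
               "stratified folds")
})

test_that("bag-fraction selection picks the lower CV deviance and breaks ties low", {
  d <- make_logit_data(35, n = 80, p = 3, beta = c(2, -1, 0.5))
  p <- brt_params(learning_rate = 0.05, tree_complexity = 2, min_obs = 5,
                  n_folds = 4, step_size = 10, max_trees = 60, patience = 2,
                  seed = 6)
  sel <- suppressWarnings(select_bag_fraction(d$X, d$y, params = p,
                                              candidates = c(0.5, 0.75)))
  expect_equal(sel$params$bag_fraction,
               as.numeric(names(which.min(sel$cv_deviance))))
  expect_equal(mean(sel$model$training_summary$cv$per_fold_deviance),
               min(sel$cv_deviance))
  # singleton candidate set is returned trivially
  sel1 <- suppressWarnings(select_bag_fraction(d$X, d$y, params = p,
                                               candidates = 0.75))
  expect_equal(sel1$params$bag_fraction, 0.75)
  # identical candidates tie -> first (they are equal, so index 1)
  sel2 <- suppressWarnings(select_bag_fraction(d$X, d$y, params = p,
                                               candidates = c(0.6, 0.6)))
  expect_equal(sel2$params$bag_fraction, 0.6)
})

test_that("JSON serialization round-trips predictions", {
  d <- make_logit_data(36, n = 30)
  m <- fit_boosted_trees(d$X, d$y, params = deep_params(), n_trees = 12)
  f <- tempfile(fileext = ".json")
  brt_to_json(m, f)
  m2 <- brt_from_json(f)
  expect_equal(predict(m2, d$X, n_trees = 12), predict(m), tolerance = 1e-12)
})
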