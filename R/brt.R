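#' Regularization parameters for boosted regression trees
#'
#' @param learning_rate shrinkage applied to every tree's contribution
#'   (0 < lr <= 1). Small values require more trees; the conventional rule of
#'   thumb is to pick a rate that lets the selected model reach at least
#'   1000 trees.
#' @param tree_complexity maximum interaction depth of each tree: a depth-k
#'   tree can represent up to k-way interactions. Trees are grown best-first
#'   by split gain up to `2^tree_complexity` terminal nodes.
#' @param bag_fraction fraction of training rows drawn without replacement at
#'   each boosting iteration (stochastic gradient boosting).
#' @param n_folds cross-validation folds for [gbm_step_fit()].
#' @param step_size trees added per cross-validation evaluation step.
#' @param max_trees upper bound on the ensemble size.
#' @param min_obs minimum number of rows on each side of a split.
#' @param patience evaluation steps without improvement of the mean held-out
#'   deviance before the stepwise search stops.
#' @param seed integer seed controlling fold assignment and bagging; `NULL`
#'   leaves the caller's RNG stream untouched.
#' @return object of class `brt_params`.
#' @export
brt_params <- function(learning_rate = 0.001, tree_complexity = 5,
                       bag_fraction = 0.5, n_folds = 10, step_size = 50,
                       max_trees = 10000, min_obs = 10, patience = 5,
                       seed = 1) {
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop_bad_arg("`learning_rate` must be in (0, 1]")
  if (!is_count(tree_complexity) || tree_complexity < 1)
    stop_bad_arg("`tree_complexity` must be an integer >= 1")
  if (!is.numeric(bag_fraction) || bag_fraction <= 0 || bag_fraction > 1)
    stop_bad_arg("`bag_fraction` must be in (0, 1]")
  if (!is_count(n_folds) || n_folds < 2)
    stop_bad_arg("`n_folds` must be an integer >= 2")
  if (!is_count(step_size) || step_size < 1 || !is_count(max_trees) ||
      max_trees < step_size)
    stop_bad_arg("`step_size`/`max_trees` invalid")
  if (!is_count(min_obs) || min_obs < 1)
    stop_bad_arg("`min_obs` must be an integer >= 1")
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 min_obs = as.integer(min_obs),
                 patience = as.integer(patience), seed = seed),
            class = "brt_params")
}

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop_bad_arg("`X` must be a numeric matrix or data.frame")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

check_xyw <- function(X, y, w) {
  if (length(y) != nrow(X)) stop_bad_arg("rows of `X` and `y` disagree")
  if (!all(y %in% c(0, 1))) stop_bad_arg("`y` must be binary 0/1")
  if (length(unique(y)) < 2)
    stop_bad_arg("`y` has a single class; boosting needs both")
  if (length(w) != length(y)) stop_bad_arg("`w` must match `y` in length")
  if (any(!is.finite(w)) || any(w <= 0))
    stop_bad_arg("weights must be positive and finite")
}

# raw fit without touching the RNG seed; w is normalized to mean 1 here
# (matching the internal normalization of classical gbm), which makes
# predictions exactly invariant to rescaling all weights.
boost_fit_raw <- function(X, y, w, params, n_trees, F_init = NULL) {
  wn <- w * length(w) / sum(w)
  intercept <- stats::qlogis(sum(wn * y) / sum(wn))
  if (is.null(F_init)) F_init <- rep(intercept, length(y))
  fit <- cpp_boost(X, as.numeric(y), wn, F_init, params$learning_rate,
                   params$tree_complexity, 2L^params$tree_complexity,
                   params$min_obs, params$bag_fraction, as.integer(n_trees))
  list(intercept = intercept, trees = fit$trees, F = fit$F,
       train_deviance = fit$train_deviance)
}

new_brt_model <- function(intercept, trees, params, n_trees_used, X, y, w,
                          training_summary) {
  structure(list(intercept = intercept, trees = trees, params = params,
                 n_trees_used = n_trees_used, var_names = colnames(X),
                 X = X, y = y, w = w, training_summary = training_summary),
            class = "brt_model")
}

#' Fit a weighted stochastic gradient-boosted tree ensemble
#'
#' Bernoulli-loss gradient boosting: the model starts from
#' `logit(sum(w*y)/sum(w))`; at every iteration a regression tree of depth at
#' most `tree_complexity` is fit by weighted least squares to the current
#' gradient (`y - p`) on a `bag_fraction` subsample drawn without
#' replacement, its terminal values are replaced by the weighted Newton step
#' `sum(w*(y-p)) / (sum(w*p*(1-p)) + 1e-6)`, and its contribution is shrunk
#' by `learning_rate`. The per-iteration weighted training deviance is
#' recorded.
#'
#' @param X numeric predictor matrix or data.frame.
#' @param y binary response (both classes must be present).
#' @param w positive per-row weights (default 1); only weight ratios matter.
#' @param params a [brt_params()] object.
#' @param n_trees number of boosting iterations.
#' @return object of class `brt_model`.
#' @export
fit_boosted_trees <- function(X, y, w = NULL, params = brt_params(),
                              n_trees = 100) {
  X <- as_predictor_matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  check_xyw(X, y, w)
  fit <- with_seed(params$seed, boost_fit_raw(X, y, w, params, n_trees))
  new_brt_model(fit$intercept, fit$trees, params, n_trees, X, y, w,
                training_summary = list(train_deviance = fit$train_deviance))
}

#' Predict occurrence probabilities from a fitted ensemble
#'
#' @param object a `brt_model`.
#' @param newdata predictor matrix/data.frame containing the training
#'   predictors; defaults to the training data.
#' @param n_trees number of leading trees to use (default: the model's
#'   `n_trees_used`); 0 gives the intercept-only prediction.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @export
predict.brt_model <- function(object, newdata = NULL, n_trees = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$X
  newdata <- as_predictor_matrix(newdata)
  missing <- setdiff(object$var_names, colnames(newdata))
  if (length(missing) > 0)
    stop_bad_arg("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
  newdata <- newdata[, object$var_names, drop = FALSE]
  if (is.null(n_trees)) n_trees <- object$n_trees_used
  if (n_trees > length(object$trees))
    stop_bad_arg("n_trees = ", n_trees, " exceeds the ", length(object$trees),
                 " fitted trees")
  f <- object$intercept +
    cpp_predict_trees(object$trees, newdata, as.integer(n_trees))
  if (type == "link") f else stats::plogis(f)
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("<brt_model> %d trees (of %d fitted), %d predictors, lr = %g, tc = %d, bag = %g\n",
              x$n_trees_used, length(x$trees), length(x$var_names),
              x$params$learning_rate, x$params$tree_complexity,
              x$params$bag_fraction))
  cv <- x$training_summary$cv
  if (!is.null(cv))
    cat(sprintf("  CV (%d folds): mean held-out deviance %.4f, mean AUC %.4f at %d trees\n",
                length(cv$per_fold_deviance), mean(cv$per_fold_deviance),
                mean(cv$per_fold_auc), x$n_trees_used))
  invisible(x)
}

# class-stratified fold assignment (expects the RNG already seeded)
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    if (length(idx) < k)
      stop_bad_arg("cannot build ", k, " stratified folds: class ", cls,
                   " has only ", length(idx), " rows (fold sizes ",
                   paste(table(cut(seq_along(idx), k)), collapse = "/"), ")")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# held-out deviance convention: -2 * sum(w * ll) / n (per observation, raw
# weights), the convention of the classical BRT toolchain; see the package
# vignette for why this, and not the per-unit-weight form, reproduces the
# weighted-background calibration gain.
holdout_deviance <- function(p, y, w) {
  p <- clamp01(p)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p))) / length(y)
}

#' Stepwise cross-validated selection of the ensemble size
#'
#' Grows, for each of `n_folds` class-stratified folds, a boosted ensemble in
#' increments of `step_size` trees, tracking the mean held-out weighted
#' deviance; the search stops once the mean held-out deviance has not
#' improved for `patience` consecutive steps (or at `max_trees`). The
#' selected size `n_trees_used` is the candidate minimizing the mean
#' held-out deviance; per-fold AUC and deviance at that size are retained
#' and the returned model is refit on all rows. A warning is raised when
#' fewer than 1000 trees are selected (the conventional rule of thumb for a
#' learning rate that is too aggressive).
#'
#' @inheritParams fit_boosted_trees
#' @return a `brt_model` whose `training_summary$cv` holds the fold
#'   assignment, the deviance trace (`n_trees`, `mean_cv_deviance`), per-fold
#'   AUC/deviance at `n_trees_used`, and `n_trees_used` itself.
#' @export
gbm_step_fit <- function(X, y, w = NULL, params = brt_params()) {
  X <- as_predictor_matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  check_xyw(X, y, w)
  with_seed(params$seed, gbm_step_fit_raw(X, y, w, params))
}

gbm_step_fit_raw <- function(X, y, w, params) {
  k <- params$n_folds
  fold <- make_folds(y, k)
  folds <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); ho <- which(fold == f)
    wn <- w[tr] * length(tr) / sum(w[tr])
    intercept <- stats::qlogis(sum(wn * y[tr]) / sum(wn))
    list(tr = tr, ho = ho, wn = wn, intercept = intercept,
         F_tr = rep(intercept, length(tr)),
         F_ho = rep(intercept, length(ho)), trees = list())
  })

  step <- params$step_size
  max_steps <- params$max_trees %/% step
  trace <- numeric(0)
  best_step <- 0L
  for (s in seq_len(max_steps)) {
    dev_f <- numeric(k)
    for (f in seq_len(k)) {
      fd <- folds[[f]]
      fit <- cpp_boost(X[fd$tr, , drop = FALSE], as.numeric(y[fd$tr]), fd$wn,
                       fd$F_tr, params$learning_rate, params$tree_complexity,
                       2L^params$tree_complexity, params$min_obs,
                       params$bag_fraction, step)
      fd$trees <- c(fd$trees, fit$trees)
      fd$F_tr <- fit$F
      fd$F_ho <- fd$F_ho +
        cpp_predict_trees(fit$trees, X[fd$ho, , drop = FALSE], step)
      folds[[f]] <- fd
      dev_f[f] <- holdout_deviance(stats::plogis(fd$F_ho), y[fd$ho], w[fd$ho])
    }
    trace[s] <- mean(dev_f)
    if (best_step == 0L || trace[s] < trace[best_step]) best_step <- s
    if (s - best_step >= params$patience) break
  }
  n_used <- best_step * step

  per_fold_auc <- numeric(k)
  per_fold_dev <- numeric(k)
  for (f in seq_len(k)) {
    fd <- folds[[f]]
    p_ho <- stats::plogis(fd$intercept +
      cpp_predict_trees(fd$trees, X[fd$ho, , drop = FALSE], n_used))
    per_fold_auc[f] <- auc(p_ho, y[fd$ho])
    per_fold_dev[f] <- holdout_deviance(p_ho, y[fd$ho], w[fd$ho])
  }

  final <- boost_fit_raw(X, y, w, params, n_used)
  if (n_used < 1000)
    warning("selected ensemble has ", n_used, " trees (< 1000); consider a ",
            "smaller learning rate", call. = FALSE)
  cv <- list(fold = fold,
             trace = data.frame(n_trees = seq_along(trace) * step,
                                mean_cv_deviance = trace),
             per_fold_auc = per_fold_auc, per_fold_deviance = per_fold_dev,
             n_trees_used = n_used,
             fold_models = lapply(folds, function(fd)
               list(intercept = fd$intercept, trees = fd$trees, ho = fd$ho)))
  new_brt_model(final$intercept, final$trees, params, n_used, X, y, w,
                training_summary = list(train_deviance = final$train_deviance,
                                        cv = cv))
}

#' Choose the bag fraction by cross-validated deviance
#'
#' Runs [gbm_step_fit()] once per candidate bag fraction and keeps the
#' candidate whose selected model attains the lowest mean held-out deviance;
#' exact ties go to the smaller bag fraction.
#'
#' @inheritParams fit_boosted_trees
#' @param candidates bag fractions to try (default `c(0.5, 0.75)`).
#' @return list with `params` (the winning [brt_params()]), `model` (its
#'   fitted `brt_model`) and `cv_deviance` (named mean held-out deviances).
#' @export
select_bag_fraction <- function(X, y, w = NULL, params = brt_params(),
                                candidates = c(0.5, 0.75)) {
  if (length(candidates) == 0) stop_bad_arg("`candidates` must be non-empty")
  candidates <- sort(candidates)
  fits <- list()
  devs <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    p_i <- params
    p_i$bag_fraction <- candidates[i]
    fits[[i]] <- gbm_step_fit(X, y, w, p_i)
    devs[i] <- mean(fits[[i]]$training_summary$cv$per_fold_deviance)
  }
  best <- which.min(devs)   # first minimum = smallest bag fraction on ties
  list(params = fits[[best]]$params, model = fits[[best]],
       cv_deviance = stats::setNames(devs, format(candidates)))
}
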