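#' Relative influence of the predictors
#'
#' Sums, over the first `n_trees` trees of the ensemble, the weighted
#' squared-improvement gain of every split on each predictor, and normalizes
#' to percentages (descending, name-alphabetical on ties). Predictors never
#' selected for splitting score exactly 0.
#'
#' @param model a `brt_model` with at least one tree.
#' @param n_trees number of leading trees to use (default `n_trees_used`).
#' @return data.frame with columns `predictor` and `contribution`
#'   (percentages summing to 100).
#' @export
relative_influence <- function(model, n_trees = NULL) {
  stopifnot(inherits(model, "brt_model"))
  if (is.null(n_trees)) n_trees <- model$n_trees_used
  if (n_trees < 1 || length(model$trees) == 0)
    stop_bad_arg("relative influence needs a non-empty ensemble")
  gains <- stats::setNames(numeric(length(model$var_names)), model$var_names)
  for (t in seq_len(n_trees)) {
    tree <- model$trees[[t]]
    internal <- tree[, 1] >= 0
    if (!any(internal)) next
    v <- model$var_names[tree[internal, 1] + 1]
    g <- tree[internal, 5]
    for (i in seq_along(v)) gains[[v[i]]] <- gains[[v[i]]] + g[i]
  }
  total <- sum(gains)
  contribution <- if (total == 0) rep(0, length(gains)) else 100 * gains / total
  out <- data.frame(predictor = names(gains), contribution = contribution,
                    row.names = NULL)
  out[order(-out$contribution, out$predictor), , drop = FALSE]
}

pd_grid_for <- function(model, predictors, grid_points, grid) {
  if (!is.null(grid)) {
    if (length(predictors) == 1) {
      g <- matrix(as.numeric(unlist(grid)), ncol = 1)
    } else {
      if (is.list(grid) && !is.data.frame(grid) && length(grid) == 2)
        grid <- expand.grid(grid[[1]], grid[[2]])
      g <- as.matrix(grid)
    }
  } else if (length(predictors) == 1) {
    xr <- range(model$X[, predictors])
    g <- matrix(seq(xr[1], xr[2], length.out = grid_points), ncol = 1)
  } else {
    qs <- lapply(predictors, function(p)
      unique(as.numeric(stats::quantile(model$X[, p],
                                        probs = seq(0, 1, length.out = grid_points),
                                        type = 7))))
    g <- as.matrix(expand.grid(qs[[1]], qs[[2]]))
  }
  colnames(g) <- predictors
  g
}

#' Partial dependence of the modelled response on one or two predictors
#'
#' Weighted tree traversal: within every tree, splits on a target predictor
#' follow the branch dictated by the grid value, while splits on the other
#' predictors send the training rows down both branches according to their
#' own values, each leaf contributing its value times the training weight
#' mass reaching it. This is exactly the training-set average prediction
#' with the target predictor(s) clamped to the grid value, computed without
#' materializing clamped datasets. One predictor gives a curve on an evenly
#' spaced grid across the observed range; two predictors give a surface on a
#' lattice of within-range quantile levels.
#'
#' @param model a `brt_model`.
#' @param predictors one or two predictor names used in training.
#' @param grid_points grid resolution per predictor (default 50 for curves,
#'   20 for surfaces).
#' @param grid optional explicit grid: a numeric vector (one predictor), or
#'   a two-column matrix/data.frame or list of two level vectors.
#' @param scale `"probability"` (relative likelihood of occurrence, the
#'   plotting scale) or `"logit"`.
#' @return data.frame with the grid columns and `response`; attributes
#'   `scale` and `predictors`.
#' @export
partial_dependence <- function(model, predictors, grid_points = NULL,
                               grid = NULL, scale = c("probability", "logit")) {
  stopifnot(inherits(model, "brt_model"))
  scale <- match.arg(scale)
  if (!length(predictors) %in% 1:2)
    stop_bad_arg("`predictors` must name 1 or 2 predictors")
  missing <- setdiff(predictors, model$var_names)
  if (length(missing) > 0)
    stop_bad_arg("unknown predictor(s): ", paste(missing, collapse = ", "))
  if (is.null(grid_points))
    grid_points <- if (length(predictors) == 1) 50 else 20
  g <- pd_grid_for(model, predictors, grid_points, grid)
  cols <- match(predictors, model$var_names) - 1L
  wn <- model$w * length(model$w) / sum(model$w)
  f <- model$intercept +
    cpp_partial_dependence(model$trees, as.integer(model$n_trees_used),
                           model$X, wn, as.integer(cols), g)
  out <- as.data.frame(g)
  out$response <- if (scale == "probability") stats::plogis(f) else f
  attr(out, "scale") <- scale
  attr(out, "predictors") <- predictors
  out
}

#' Pairwise interaction size of two predictors
#'
#' Computes the two-predictor partial dependence (logit scale) on a
#' `grid_points x grid_points` lattice of within-range quantile levels, fits
#' by least squares the additive surface with row and column main effects,
#' and reports `1000 x` the mean squared residual — the departure of the
#' joint response from additivity of the two marginal effects. The score is
#' 0 for any pair containing a predictor never used in splits and for
#' additive ensembles (e.g. depth-1 trees).
#'
#' @param model a `brt_model`.
#' @param predictor_i,predictor_j predictor names.
#' @param grid_points quantile levels per predictor (default 20).
#' @return non-negative scalar.
#' @export
interaction_size <- function(model, predictor_i, predictor_j,
                             grid_points = 20) {
  pd <- partial_dependence(model, c(predictor_i, predictor_j),
                           grid_points = grid_points, scale = "logit")
  z <- pd$response
  if (stats::sd(z) == 0) return(0)
  fr <- factor(pd[[predictor_i]])
  fc <- factor(pd[[predictor_j]])
  fit <- stats::lm.fit(stats::model.matrix(~ fr + fc), z)
  1000 * mean(fit$residuals^2)
}

#' Ranked contributions and all pairwise interactions among the top k
#'
#' @param model a `brt_model`.
#' @param k how many top predictors to keep (>= 1, at most the number of
#'   predictors).
#' @param grid_points lattice resolution passed to [interaction_size()].
#' @return list with `contributions` (the k top rows of
#'   [relative_influence()], ties broken by predictor name) and
#'   `interactions` (data.frame `predictor_i`, `predictor_j`, `score`,
#'   descending; `k*(k-1)/2` rows).
#' @export
top_k_report <- function(model, k = 3, grid_points = 20) {
  if (!is_count(k) || k < 1) stop_bad_arg("`k` must be an integer >= 1")
  ri <- relative_influence(model)
  if (k > nrow(ri)) stop_bad_arg("`k` exceeds the number of predictors")
  top <- ri[seq_len(k), , drop = FALSE]
  if (k < 2) {
    inter <- data.frame(predictor_i = character(0), predictor_j = character(0),
                        score = numeric(0))
  } else {
    pairs <- utils::combn(top$predictor, 2)
    inter <- data.frame(predictor_i = pairs[1, ], predictor_j = pairs[2, ],
                        score = apply(pairs, 2, function(pr)
                          interaction_size(model, pr[1], pr[2],
                                           grid_points = grid_points)))
    inter <- inter[order(-inter$score), , drop = FALSE]
  }
  list(contributions = top, interactions = inter)
}
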