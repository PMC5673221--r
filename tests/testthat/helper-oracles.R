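# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain, slow R (data held in vectors,
# exhaustive scans) and share no code with the package internals.

# ---- gradient boosting oracle (bag fraction 1 only) ----
# Mirrors the stated update rule: weights normalized to mean 1, intercept at
# the weighted-mean logit, trees grown best-first by weighted-LS gain on the
# gradient y - p with midpoint splits and min_obs rows per side, terminal
# Newton steps sum(w*(y-p)) / (sum(w*p*(1-p)) + 1e-6), shrunk by the
# learning rate.
oracle_boost <- function(X, y, w = NULL, learning_rate, tree_complexity,
                         min_obs = 1, n_trees) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  w <- w * n / sum(w)
  Fv <- rep(qlogis(sum(w * y) / sum(w)), n)

  best_split_of <- function(rows, r) {
    best <- list(gain = 0, var = NA, split = NA)
    sw <- sum(w[rows]); swr <- sum(w[rows] * r[rows])
    for (j in seq_len(ncol(X))) {
      x <- X[rows, j]
      ord <- order(x)
      xo <- x[ord]; ro <- rows[ord]
      swl <- cumsum(w[ro]); swrl <- cumsum(w[ro] * r[ro])
      m <- length(rows)
      for (k in seq_len(m - 1)) {
        if (xo[k] >= xo[k + 1]) next
        if (k < min_obs || (m - k) < min_obs) next
        gain <- swrl[k]^2 / swl[k] +
          (swr - swrl[k])^2 / (sw - swl[k]) - swr^2 / sw
        if (gain > best$gain && gain > 1e-10) {
          best <- list(gain = gain, var = j, split = (xo[k] + xo[k + 1]) / 2)
        }
      }
    }
    best
  }

  for (t in seq_len(n_trees)) {
    p <- plogis(Fv)
    r <- y - p
    leaves <- list(list(rows = seq_len(n), depth = 0))
    for (i in seq_along(leaves))
      leaves[[i]]$best <- if (tree_complexity > 0)
        best_split_of(leaves[[i]]$rows, r) else list(gain = 0)
    repeat {
      if (length(leaves) >= 2^tree_complexity) break
      gains <- vapply(leaves, function(l) l$best$gain, numeric(1))
      if (max(gains) <= 0) break
      i <- which.max(gains)            # first max = creation order tie-break
      nd <- leaves[[i]]
      go_left <- X[nd$rows, nd$best$var] < nd$best$split
      lc <- list(rows = nd$rows[go_left], depth = nd$depth + 1)
      rc <- list(rows = nd$rows[!go_left], depth = nd$depth + 1)
      for (ch in c("lc", "rc")) {
        child <- get(ch)
        child$best <- if (child$depth < tree_complexity)
          best_split_of(child$rows, r) else list(gain = 0)
        assign(ch, child)
      }
      leaves <- c(leaves[-i], list(lc, rc))
      # re-insertion order differs from the package's node vector, but
      # selection is by gain with first-max ties, which is order-free when
      # gains are distinct (continuous data)
    }
    for (l in leaves) {
      rows <- l$rows
      val <- sum(w[rows] * r[rows]) /
        (sum(w[rows] * p[rows] * (1 - p[rows])) + 1e-6)
      Fv[rows] <- Fv[rows] + learning_rate * val
    }
  }
  plogis(Fv)
}

# ---- trapezoidal ROC AUC ----
auc_trapezoid <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(ths, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# ---- brute-force partial dependence by clamping ----
oracle_pd <- function(model, predictors, grid) {
  grid <- as.matrix(grid)
  wn <- model$w / sum(model$w)
  vapply(seq_len(nrow(grid)), function(g) {
    Xc <- model$X
    for (j in seq_along(predictors)) Xc[, predictors[j]] <- grid[g, j]
    sum(wn * predict(model, Xc, type = "link"))
  }, numeric(1))
}

# ---- confusion-matrix TSS by direct enumeration ----
oracle_tss_at <- function(scores, labels, threshold) {
  tp <- sum(labels == 1 & scores >= threshold)
  fn <- sum(labels == 1 & scores < threshold)
  tn <- sum(labels == 0 & scores < threshold)
  fp <- sum(labels == 0 & scores >= threshold)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# ---- small synthetic fixtures ----
make_test_stack <- function(seed = 1, n = 24, layers = 6)
  make_env_stack(n, n, layers, correlation = 0.4, seed = seed)

make_disjoint_group <- function(seed = 1, counts = c(a = 6, b = 9, c = 12)) {
  # points on distinct integer cells, no environmental structure needed
  set.seed(seed)
  total <- sum(counts)
  cells <- sample.int(900, total)
  xy <- data.frame(x = (cells - 1) %% 30 + 0.5,
                   y = (cells - 1) %/% 30 + 0.5)
  idx <- rep(seq_along(counts), counts)
  sets <- lapply(seq_along(counts), function(i) {
    data.frame(species = names(counts)[i], x = xy$x[idx == i],
               y = xy$y[idx == i])
  })
  names(sets) <- names(counts)
  target_group(sets)
}

make_logit_data <- function(seed, n = 60, p = 4, beta = c(2, -1.5, rep(0, 2)),
                            intercept = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  prob <- plogis(intercept + X %*% beta[seq_len(p)])
  y <- rbinom(n, 1, prob)
  # guarantee both classes
  if (sum(y) == 0) y[which.max(prob)] <- 1
  if (sum(y) == n) y[which.min(prob)] <- 0
  list(X = X, y = y)
}
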