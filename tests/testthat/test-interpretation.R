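fit_small <- function(seed, n = 60, p = 4, beta = c(2, -1.5, 0, 0),
                      depth = 2, trees = 30, lr = 0.15) {
  d <- make_logit_data(seed, n = n, p = p, beta = beta)
  fit_boosted_trees(d$X, d$y,
                    params = brt_params(learning_rate = lr,
                                        tree_complexity = depth,
                                        bag_fraction = 1, min_obs = 3,
                                        seed = 1),
                    n_trees = trees)
}

test_that("relative influence isolates the informative predictor and sums to 100", {
  m <- fit_small(60, p = 6, beta = c(3, 0, 0, 0, 0, 0))
  ri <- relative_influence(m)
  expect_equal(sum(ri$contribution), 100, tolerance = 1e-6)
  expect_true(all(ri$contribution >= 0))
  expect_equal(ri$predictor[1], "V1")
  expect_gt(ri$contribution[1], 50)

  # a predictor never split on contributes exactly 0
  used <- unique(unlist(lapply(m$trees, function(tr)
    m$var_names[tr[tr[, 1] >= 0, 1] + 1])))
  unused <- setdiff(m$var_names, used)
  if (length(unused) > 0)
    expect_true(all(ri$contribution[ri$predictor %in% unused] == 0))
})

test_that("partial dependence by traversal equals brute-force clamping", {
  m <- fit_small(61, depth = 3, trees = 20)
  for (pred in c("V1", "V2")) {
    g <- seq(min(m$X[, pred]), max(m$X[, pred]), length.out = 11)
    pd <- partial_dependence(m, pred, grid = g, scale = "logit")
    expect_lt(max(abs(pd$response - oracle_pd(m, pred, matrix(g)))), 1e-9)
  }
  # two-predictor surface
  g2 <- expand.grid(V1 = seq(-1, 1, length.out = 6),
                    V2 = seq(-1, 1, length.out = 6))
  pd2 <- partial_dependence(m, c("V1", "V2"), grid = g2, scale = "logit")
  expect_lt(max(abs(pd2$response - oracle_pd(m, c("V1", "V2"), g2))), 1e-9)

  expect_error(partial_dependence(m, "V9"), "unknown predictor")
})

test_that("a depth-1 split yields a two-level step at the split point", {
  set.seed(62)
  X <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("V1", "V2")))
  y <- as.numeric(X[, 1] > 0.5)
  m <- fit_boosted_trees(X, y,
                         params = brt_params(learning_rate = 1,
                                             tree_complexity = 1,
                                             bag_fraction = 1, min_obs = 5,
                                             seed = 1), n_trees = 1)
  tr <- m$trees[[1]]
  split <- tr[1, 2]
  pd <- partial_dependence(m, "V1", grid = seq(0, 1, by = 0.05),
                           scale = "logit")
  expect_equal(length(unique(round(pd$response, 12))), 2)
  expect_lt(max(pd$response[pd$V1 < split]), min(pd$response[pd$V1 >= split]))
})

test_that("depth-1 ensembles are additive: 2-D PD = sum of 1-D PDs (logit)", {
  m <- fit_small(63, depth = 1, trees = 40, beta = c(2, -2, 0, 0))
  g1 <- seq(-1, 1, length.out = 7)
  pd_a <- partial_dependence(m, "V1", grid = g1, scale = "logit")$response
  pd_b <- partial_dependence(m, "V2", grid = g1, scale = "logit")$response
  pd_ab <- partial_dependence(m, c("V1", "V2"),
                              grid = expand.grid(g1, g1),
                              scale = "logit")$response
  joint <- outer(pd_a, pd_b, `+`)          # grid varies V1 fastest
  resid <- pd_ab - as.vector(joint) + m$intercept
  expect_lt(max(abs(resid - mean(resid))), 1e-9)
})

test_that("interaction sizes separate additive from multiplicative responses", {
  # generous sample and slow learning so the additive model is learned
  # cleanly; the product term is strong so a true interaction dominates
  gen <- function(seed, interactive) {
    set.seed(seed)
    n <- 600
    X <- matrix(runif(n * 3, -1, 1), n, 3,
                dimnames = list(NULL, c("V1", "V2", "V3")))
    f <- if (interactive) 8 * X[, 1] * X[, 2] else 2 * X[, 1] + 2 * X[, 2]
    y <- rbinom(n, 1, plogis(f))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    fit_boosted_trees(X, y,
                      params = brt_params(learning_rate = 0.04,
                                          tree_complexity = 2,
                                          bag_fraction = 1, min_obs = 30,
                                          seed = 1), n_trees = 250)
  }
  add <- interaction_size(gen(64, FALSE), "V1", "V2")
  mult <- interaction_size(gen(64, TRUE), "V1", "V2")
  expect_lt(add, 0.05 * mult)

  # the interacting pair outranks pairs with the inert predictor in most seeds
  wins <- 0L
  for (sd in 1:10) {
    m <- gen(200 + sd, TRUE)
    sc <- c(v12 = interaction_size(m, "V1", "V2"),
            v13 = interaction_size(m, "V1", "V3"),
            v23 = interaction_size(m, "V2", "V3"))
    if (names(which.max(sc)) == "v12") wins <- wins + 1L
  }
  expect_gt(wins, 5)
})

test_that("interaction score vanishes for unused predictors and additive ensembles", {
  m <- fit_small(65, p = 8, beta = c(3, rep(0, 7)), depth = 2, trees = 8)
  used <- unique(unlist(lapply(m$trees, function(tr)
    m$var_names[tr[tr[, 1] >= 0, 1] + 1])))
  unused <- setdiff(m$var_names, used)
  expect_gt(length(unused), 0)
  expect_equal(interaction_size(m, used[1], unused[1]), 0)

  # depth-1 trees give a structurally additive ensemble: the interaction
  # score is numerically zero at every lattice resolution
  madd <- fit_small(67, depth = 1, trees = 50, beta = c(2, -2, 0, 0))
  for (g in c(5, 10, 20))
    expect_lt(interaction_size(madd, "V1", "V2", grid_points = g), 1e-9)
})

test_that("top-k reports rank deterministically and cover all pairs", {
  m <- fit_small(66, p = 5, beta = c(2, -1.5, 1, 0, 0), depth = 2,
                 trees = 40)
  rep3 <- top_k_report(m, 3, grid_points = 8)
  expect_equal(nrow(rep3$contributions), 3)
  expect_equal(nrow(rep3$interactions), 3)
  expect_true(all(diff(rep3$contributions$contribution) <= 0))
  expect_true(all(diff(rep3$interactions$score) <= 0))

  rep1 <- top_k_report(m, 1)
  expect_equal(nrow(rep1$contributions), 1)
  expect_equal(nrow(rep1$interactions), 0)
  expect_error(top_k_report(m, 0), ">= 1")
  expect_error(top_k_report(m, 99), "exceeds")
})
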