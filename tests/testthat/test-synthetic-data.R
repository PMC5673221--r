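test_that("generated stacks honour the requested inter-layer correlation", {
  low <- make_env_stack(50, 50, 5, 0.0, seed = 1)
  cm <- cor(sapply(low$layers[setdiff(low$layer_names, c("SLOPE", "ASPECT"))],
                   as.vector))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.25)

  high <- make_env_stack(50, 50, 3 + 2, 0.9, seed = 1)
  keep <- setdiff(high$layer_names, c("SLOPE", "ASPECT"))
  cm2 <- cor(sapply(high$layers[keep], as.vector))
  expect_gt(mean(cm2[upper.tri(cm2)]), 0.6)
})

test_that("stacks are seed-deterministic and structurally valid", {
  a <- make_env_stack(20, 30, 6, 0.5, seed = 42)
  b <- make_env_stack(20, 30, 6, 0.5, seed = 42)
  expect_identical(a, b)
  c <- make_env_stack(20, 30, 6, 0.5, seed = 43)
  expect_false(identical(a$layers[[1]], c$layers[[1]]))

  expect_true(all(a$layers$SLOPE >= 0))
  expect_true(all(a$layers$ASPECT >= 0 & a$layers$ASPECT < 360))
  for (nm in a$layer_names) expect_gt(sd(a$layers[[nm]]), 0)
  expect_identical(a$layer_names, c("BIO1", "BIO2", "BIO3", "ALT", "SLOPE",
                                    "ASPECT"))
  expect_error(make_env_stack(5, 50, 4), "must be integers >= 10")
  expect_error(make_env_stack(20, 20, 2), ">= 3")
})

test_that("suitability surfaces follow the logistic linear model", {
  st <- make_test_stack(2)
  expect_error(virtual_species("zero", c(BIO1 = 0, BIO2 = 0), 5),
               "non-zero")
  s0 <- suitability_surface(st, virtual_species("f", c(BIO1 = 1e-30), 5))
  expect_true(all(abs(s0 - 0.5) < 1e-15))

  sat <- suitability_surface(st, virtual_species("sat", c(BIO1 = 1e-30), 5,
                                                 intercept = 50))
  expect_true(all(sat > 0.999))

  mono <- suitability_surface(st, virtual_species("m", c(BIO1 = 1), 5))
  o <- order(as.vector(st$layers$BIO1))
  expect_true(all(diff(as.vector(mono)[o]) >= 0))

  expect_error(
    suitability_surface(st, virtual_species("bad", c(NOPE = 1), 5)),
    "NOPE")

  with_int <- virtual_species("i", c(BIO1 = 0.5), 5,
                              interaction_terms = list(list("BIO1", "BIO2", 0.3)))
  si <- suitability_surface(st, with_int)
  manual <- plogis(0.5 * st$layers$BIO1 + 0.3 * st$layers$BIO1 * st$layers$BIO2)
  expect_equal(as.vector(si), as.vector(manual), tolerance = 1e-12)
})

test_that("presence sampling is proportional, exhaustive and exclusion-aware", {
  suit <- matrix(1, 10, 10)
  all_pts <- sample_presences(suit, 100, seed = 1)
  expect_equal(nrow(unique(all_pts[, c("x", "y")])), 100)

  zoned <- matrix(0, 10, 10)
  zoned[1:3, ] <- 1                       # region A = rows 1-3 (y < 3)
  pts <- sample_presences(zoned, 10, seed = 2)
  expect_true(all(pts$y < 3))

  expect_error(sample_presences(zoned, 31, seed = 1), "only 30 cells")

  peaked <- matrix(0.01, 20, 20)
  peaked[8:12, 8:12] <- 1
  for (sd in 1:20) {
    pts <- sample_presences(peaked, 50, seed = sd)
    at <- peaked[cbind(ceiling(pts$y), ceiling(pts$x))]
    expect_gt(mean(at), mean(peaked))
  }
})

test_that("target groups conserve counts and enforce distinct cells", {
  st <- make_test_stack(3, n = 24, layers = 6)
  specs <- list(
    virtual_species("s1", c(BIO1 = 1), n_presences = 73),
    virtual_species("s2", c(BIO2 = 1), n_presences = 24),
    virtual_species("s3", c(BIO3 = -1), n_presences = 55),
    virtual_species("s4", c(ALT = 0.5), n_presences = 168))
  grp <- make_target_group(st, specs, seed = 9)
  expect_s3_class(grp, "target_group")
  expect_equal(grp$D, 320)
  expect_equal(vapply(grp$species_sets, nrow, integer(1)),
               c(s1 = 73, s2 = 24, s3 = 55, s4 = 168))
  pooled <- do.call(rbind, grp$species_sets)
  expect_equal(nrow(unique(pooled[, c("x", "y")])), 320)

  expect_error(virtual_species("empty", c(BIO1 = 1), n_presences = 0),
               ">= 1")
  dup <- list(virtual_species("s1", c(BIO1 = 1), 5),
              virtual_species("s1", c(BIO2 = 1), 5))
  expect_error(make_target_group(st, dup, seed = 1), "duplicate")
  expect_error(make_target_group(st, specs[1], seed = 1), "at least 2")
})
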