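test_that("UTGB counts obey a_k = D - p_k on disjoint-cell groups", {
  grp <- make_disjoint_group(7, c(a = 15, b = 8, c = 21, d = 30))
  for (sp in names(grp$species_sets)) {
    pa <- generate_utgb(grp, sp)
    p_k <- nrow(grp$species_sets[[sp]])
    # brute force: union of the other species' points
    others <- do.call(rbind,
                      grp$species_sets[setdiff(names(grp$species_sets), sp)])
    expect_equal(pa$a_k, nrow(others))
    expect_equal(pa$a_k, grp$D - p_k)
    expect_true(all(pa$weights == 1))
  }
  expect_error(generate_utgb(grp, "nope"), "not in the target group")
  solo <- target_group(grp$species_sets["a"])
  expect_error(generate_utgb(solo, "a"), ">= 2 species")
})

test_that("UTGB excludes cell-coincident points and warns on full overlap", {
  a <- data.frame(species = "a", x = c(1.5, 2.5), y = c(1.5, 1.5))
  b <- data.frame(species = "b", x = c(1.5, 2.5), y = c(1.5, 1.5))
  grp <- target_group(list(a = a, b = b))
  expect_warning(pa <- generate_utgb(grp, "a"), "empty background")
  expect_equal(pa$a_k, 0)

  # partial overlap: only the non-coincident point survives
  b2 <- data.frame(species = "b", x = c(1.5, 7.5), y = c(1.5, 1.5))
  pa2 <- generate_utgb(target_group(list(a = a, b = b2)), "a")
  expect_equal(pa2$a_k, 1)
  expect_equal(pa2$points$x, 7.5)

  # cell-based coincidence: same cell, different exact coordinates
  b3 <- data.frame(species = "b", x = c(1.2, 7.5), y = c(1.9, 1.5))
  expect_equal(generate_utgb(target_group(list(a = a, b = b3)), "a")$a_k, 2)
  expect_equal(generate_utgb(target_group(list(a = a, b = b3)), "a",
                             cell_size = 1)$a_k, 1)
})

test_that("WTGB weights are p_k/a_k and conserve total presence weight", {
  grp <- make_disjoint_group(8, c(a = 15, b = 8, c = 21, d = 30))
  for (sp in names(grp$species_sets)) {
    p_k <- nrow(grp$species_sets[[sp]])
    pa <- generate_wtgb(grp, sp)
    expect_true(all(pa$weights == p_k / pa$a_k))
    expect_lt(abs(sum(pa$weights) - p_k), 1e-9 * p_k)
  }
  # property over random group sizes
  for (sd in 1:10) {
    set.seed(sd)
    counts <- sample(3:40, sample(2:6, 1))
    names(counts) <- paste0("sp", seq_along(counts))
    g <- make_disjoint_group(sd + 100, counts)
    for (sp in names(g$species_sets)) {
      pa <- generate_wtgb(g, sp)
      p_k <- nrow(g$species_sets[[sp]])
      expect_lt(abs(sum(pa$weights) - p_k), 1e-9 * p_k)
    }
  }
  # balanced two-species group: weights collapse to 1 (identical to UTGB)
  bal <- make_disjoint_group(9, c(a = 12, b = 12))
  expect_true(all(generate_wtgb(bal, "a")$weights == 1))

  a <- data.frame(species = "a", x = 1.5, y = 1.5)
  b <- data.frame(species = "b", x = 1.5, y = 1.5)
  expect_error(suppressWarnings(
    generate_wtgb(target_group(list(a = a, b = b)), "a")),
    "empty background")
})

test_that("RDM replicates avoid presence cells, differ, and reproduce", {
  st <- make_test_stack(5, n = 24)
  pres <- sample_presences(suitability_surface(
    st, virtual_species("t", c(BIO1 = 1), 55)), 55, seed = 1, species = "t")
  reps <- generate_rdm(st, pres, n_replicates = 4, seed = 10)
  expect_length(reps, 4)
  pres_key <- paste(pres$x, pres$y)
  for (r in reps) {
    expect_equal(r$a_k, 55)
    expect_true(all(r$weights == 1))
    expect_equal(anyDuplicated(paste(r$points$x, r$points$y)), 0)
    expect_false(any(paste(r$points$x, r$points$y) %in% pres_key))
  }
  expect_false(identical(reps[[1]]$points, reps[[2]]$points))
  reps2 <- generate_rdm(st, pres, n_replicates = 4, seed = 10)
  expect_identical(lapply(reps, `[[`, "points"),
                   lapply(reps2, `[[`, "points"))
})

test_that("RDM forced selection and infeasibility behave as specified", {
  st <- make_env_stack(10, 10, 3, seed = 2)
  # presences occupy half the grid, so the p_k = 50 draw is forced to take
  # every remaining cell, whatever the seed
  all_xy <- expand.grid(x = (1:10) - 0.5, y = (1:10) - 0.5)
  pres <- data.frame(species = "t", all_xy[1:50, ])
  forced <- generate_rdm(st, pres, n_replicates = 2, seed = 1)
  free <- all_xy[51:100, ]
  for (r in forced)
    expect_setequal(paste(r$points$x, r$points$y), paste(free$x, free$y))

  too_many <- data.frame(species = "t", all_xy[1:95, ])
  expect_error(generate_rdm(st, too_many, 1, 1),
               "required 95, available non-presence cells 5")
})
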