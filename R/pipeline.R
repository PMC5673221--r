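#' Default virtual target group
#'
#' The four-species community used by the study configuration: three focal
#' species spanning a generalist-to-specialist gradient plus one filler
#' group that tops the pooled set up to `d_total` records.
#'
#' * `generalist_toad` (73 presences): broad tolerance, weak climatic
#'   preferences — hard to discriminate from any background.
#' * `slope_salamander` (24 presences): steep, north-east-facing terrain and
#'   wet cells (strong `SLOPE`, negative `ASPECT`, positive `BIO3`).
#' * `lowland_newt` (55 presences): flat, wet terrain (negative `SLOPE`,
#'   positive `BIO3`).
#' * `filler_frog_group`: mild preferences, `d_total - 152` presences, so
#'   the pooled group reaches `d_total` records.
#'
#' @param d_total pooled record count of the target group (default 320).
#' @return list of [virtual_species()].
#' @export
default_species_set <- function(d_total = 320) {
  n_filler <- d_total - (73 + 24 + 55)
  if (n_filler < 1) stop_bad_arg("`d_total` too small for the focal species")
  list(
    virtual_species("generalist_toad",
                    c(BIO2 = 2.2, ALT = -1.5, ASPECT = -0.004),
                    n_presences = 73),
    virtual_species("slope_salamander",
                    c(SLOPE = 0.5, ASPECT = -0.015, BIO3 = 1.2),
                    n_presences = 24, intercept = -4),
    virtual_species("lowland_newt",
                    c(SLOPE = -0.6, BIO3 = 1.5),
                    n_presences = 55, intercept = 1),
    virtual_species("filler_frog_group",
                    c(BIO1 = 0.5, SLOPE = -0.08),
                    n_presences = n_filler)
  )
}

#' Study configuration
#'
#' Bundles every knob of the end-to-end comparison: the synthetic landscape,
#' the virtual community, the pseudo-absence schemes, the boosting
#' regularization and the evaluation options. Defaults reproduce the study
#' conditions at desk scale: a 20 x 20 landscape of 8 correlated layers, a
#' 320-record target group with focal presence counts 73/24/55, ten
#' cross-validation folds, bag fractions 0.5/0.75 chosen by CV, four random
#' replicates, and a learning rate / tree cap (0.01 / 500) scaled to the
#' landscape size.
#'
#' @param n_rows,n_cols,n_layers,layer_correlation landscape, see
#'   [make_env_stack()].
#' @param species list of [virtual_species()] (>= 2).
#' @param focal_species labels of the modelled species.
#' @param schemes subset of `c("UTGB", "WTGB", "RDM")`.
#' @param rdm_replicates random pseudo-absence replicates (default 4).
#' @param brt a [brt_params()] object.
#' @param bag_candidates bag fractions tried per model; a single value skips
#'   the selection step.
#' @param alpha significance level of the comparison cascade.
#' @param top_k predictors kept in the interpretation report.
#' @param pd_grid_points lattice resolution for interaction sizes.
#' @param cell_area_ha per-cell area used for class extents.
#' @param moran_cell_factor coarsening factor of the Moran screening grid
#'   relative to the predictor grid.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_rows = 20, n_cols = 20, n_layers = 8,
                         layer_correlation = 0.6,
                         species = default_species_set(),
                         focal_species = c("generalist_toad",
                                           "slope_salamander",
                                           "lowland_newt"),
                         schemes = c("UTGB", "WTGB", "RDM"),
                         rdm_replicates = 4,
                         brt = brt_params(learning_rate = 0.01,
                                          tree_complexity = 5,
                                          bag_fraction = 0.5, n_folds = 10,
                                          step_size = 25, max_trees = 500,
                                          min_obs = 10, patience = 4),
                         bag_candidates = c(0.5, 0.75), alpha = 0.05,
                         top_k = 3, pd_grid_points = 20, cell_area_ha = 86,
                         moran_cell_factor = 2, seed = 1) {
  structure(list(n_rows = n_rows, n_cols = n_cols, n_layers = n_layers,
                 layer_correlation = layer_correlation, species = species,
                 focal_species = focal_species, schemes = schemes,
                 rdm_replicates = rdm_replicates, brt = brt,
                 bag_candidates = bag_candidates, alpha = alpha,
                 top_k = top_k, pd_grid_points = pd_grid_points,
                 cell_area_ha = cell_area_ha,
                 moran_cell_factor = moran_cell_factor, seed = seed),
            class = "study_config")
}

#' Validate a study configuration
#'
#' @param config a [study_config()].
#' @return data.frame with columns `field` and `problem`; zero rows iff the
#'   configuration can be run.
#' @export
validate_config <- function(config) {
  probs <- list()
  add <- function(field, problem)
    probs[[length(probs) + 1]] <<- data.frame(field = field, problem = problem)
  if (!inherits(config, "study_config")) {
    add("config", "not a study_config object")
    return(do.call(rbind, probs))
  }
  if (!is_count(config$n_rows) || config$n_rows < 10 ||
      !is_count(config$n_cols) || config$n_cols < 10)
    add("n_rows/n_cols", "grid dimensions must be integers >= 10")
  if (length(config$species) < 2)
    add("species", "at least 2 species required for a target group")
  nm <- vapply(config$species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) add("species", "duplicate species names")
  if (length(config$focal_species) < 1)
    add("focal_species", "at least one focal species required")
  missing <- setdiff(config$focal_species, nm)
  if (length(missing) > 0)
    add("focal_species", paste("not in species list:",
                               paste(missing, collapse = ", ")))
  if (length(config$schemes) < 1 ||
      !all(config$schemes %in% c("UTGB", "WTGB", "RDM")))
    add("schemes", "must be a non-empty subset of UTGB/WTGB/RDM")
  if (!is_count(config$rdm_replicates) || config$rdm_replicates < 1)
    add("rdm_replicates", "replicate count must be an integer >= 1")
  if (!inherits(config$brt, "brt_params"))
    add("brt", "must be a brt_params object")
  if (length(config$bag_candidates) < 1)
    add("bag_candidates", "must be non-empty")
  n_cells <- config$n_rows * config$n_cols
  n_total <- sum(vapply(config$species, function(s) s$n_presences, integer(1)))
  if (n_total > n_cells)
    add("species", sprintf("total presences (%d) exceed grid cells (%d)",
                           n_total, n_cells))
  out <- if (length(probs) == 0)
    data.frame(field = character(0), problem = character(0))
  else do.call(rbind, probs)
  out
}

# deterministic small sub-seed per (species, scheme, replicate)
sub_seed <- function(master, i_species, i_scheme, replicate = 0) {
  master + 1000L * i_species + 100L * i_scheme + replicate
}

fit_one <- function(X, y, w, config, seed) {
  params <- config$brt
  params$seed <- seed
  if (length(config$bag_candidates) > 1) {
    sel <- select_bag_fraction(X, y, w, params, config$bag_candidates)
    sel$model
  } else {
    params$bag_fraction <- config$bag_candidates[1]
    gbm_step_fit(X, y, w, params)
  }
}

interpret_one <- function(model, config) {
  list(contributions = relative_influence(model),
       report = top_k_report(model, k = config$top_k,
                             grid_points = config$pd_grid_points))
}

# mean of per-replicate contribution tables, re-ranked
average_contributions <- function(tabs) {
  merged <- Reduce(function(a, b) {
    m <- merge(a, b, by = "predictor")
    m$contribution <- m$contribution.x + m$contribution.y
    m[, c("predictor", "contribution")]
  }, tabs)
  merged$contribution <- merged$contribution / length(tabs)
  merged[order(-merged$contribution, merged$predictor), , drop = FALSE]
}

#' Run the full pseudo-absence comparison study
#'
#' Executes, under one master seed: synthetic landscape and target-group
#' generation; Moran's I screening of each focal occurrence set and of the
#' pooled set; per focal species and scheme, pseudo-absence generation,
#' stepwise-CV boosted-tree fitting (with bag-fraction selection),
#' fold-level evaluation, TSS threshold sweeps, interpretation and
#' projection (random replicates are averaged before mapping and
#' interpretation); and the pairwise statistical comparison cascade on AUC
#' and deviance. Failures are isolated per species x scheme combination.
#'
#' @param config a [study_config()]; invalid configurations abort with the
#'   problems from [validate_config()] in the message.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV and rasters as ESRI ASCII grids.
#' @param quiet suppress progress messages.
#' @return object of class `study_report`; see the package vignette for its
#'   structure.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, quiet = TRUE) {
  probs <- validate_config(config)
  if (nrow(probs) > 0)
    stop_bad_arg("invalid config: ",
                 paste(probs$field, probs$problem, sep = ": ",
                       collapse = "; "))
  say <- function(...) if (!quiet) message(...)
  master <- config$seed

  stack <- make_env_stack(config$n_rows, config$n_cols, config$n_layers,
                          config$layer_correlation, seed = master)
  group <- make_target_group(stack, config$species, seed = master + 101)

  # Moran's I screening on a coarsened grid
  moran_one <- function(points, label) {
    mr <- tryCatch(
      morans_i(grid_aggregate(points,
                              cell_size = stack$cell_size *
                                config$moran_cell_factor,
                              origin = stack$origin)),
      error = function(e) NULL)
    if (is.null(mr)) return(NULL)
    data.frame(set = label, I = mr$I, z_score = mr$z_score,
               p_value = mr$p_value, n_cells = mr$n_cells,
               weight_scheme = mr$weight_scheme)
  }
  pooled <- do.call(rbind, group$species_sets)
  moran <- do.call(rbind, c(
    lapply(config$focal_species,
           function(sp) moran_one(group$species_sets[[sp]], sp)),
    list(moran_one(pooled, "all_species"))))

  results <- list()
  for (i_sp in seq_along(config$focal_species)) {
    sp <- config$focal_species[i_sp]
    presences <- group$species_sets[[sp]]
    for (i_sc in seq_along(config$schemes)) {
      scheme <- config$schemes[i_sc]
      say("fitting ", sp, " / ", scheme)
      res <- tryCatch(
        run_combination(stack, group, presences, sp, scheme, config,
                        sub_seed(master, i_sp, i_sc)),
        error = function(e) list(failed = TRUE, error = conditionMessage(e)))
      results[[sp]][[scheme]] <- res
    }
  }

  comparisons <- compare_all(results, config)

  report <- structure(list(
    results = results, comparisons = comparisons, moran = moran,
    group = group, stack_meta = list(n_rows = stack$n_rows,
                                     n_cols = stack$n_cols,
                                     layers = stack$layer_names),
    provenance = list(seed = master, config = config,
                      package_version = as.character(utils::packageVersion("tgbsdm")),
                      r_version = R.version.string)
  ), class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, stack, out_dir)
  report
}

run_combination <- function(stack, group, presences, sp, scheme, config,
                            seed) {
  if (scheme %in% c("UTGB", "WTGB")) {
    pa <- if (scheme == "UTGB") generate_utgb(group, sp)
          else generate_wtgb(group, sp)
    td <- build_training_data(stack, presences, pa)
    model <- withCallingHandlers(
      fit_one(td$X, td$y, td$w, config, seed),
      warning = function(w) invokeRestart("muffleWarning"))
    cvm <- collect_cv_metrics(model, scheme, sp)
    scores <- predict(model)
    tss <- tss_profile(scores, td$y)
    interp <- interpret_one(model, config)
    raster <- project(model, stack, species = sp, scheme = scheme)
    raster <- discretize_and_areas(raster, config$cell_area_ha)
    list(scheme = scheme, species = sp, a_k = pa$a_k,
         sum_weights = sum(pa$weights), model = model, cv = cvm, tss = tss,
         contributions = interp$contributions,
         top_k = interp$report, raster = raster,
         n_trees_used = model$n_trees_used,
         bag_fraction = model$params$bag_fraction)
  } else {
    pa_sets <- generate_rdm(stack, presences, config$rdm_replicates,
                            seed = seed)
    fits <- list(); tsss <- list(); rasters <- list(); contribs <- list()
    for (r in seq_along(pa_sets)) {
      td <- build_training_data(stack, presences, pa_sets[[r]])
      m <- withCallingHandlers(
        fit_one(td$X, td$y, td$w, config, seed + r),
        warning = function(w) invokeRestart("muffleWarning"))
      fits[[r]] <- m
      tsss[[r]] <- tss_profile(predict(m), td$y)
      rasters[[r]] <- project(m, stack, species = sp, scheme = "RDM",
                              replicate_id = r)
      contribs[[r]] <- relative_influence(m)
    }
    cvm <- collect_cv_metrics(fits, "RDM", sp)
    avg_contrib <- average_contributions(contribs)
    top <- avg_contrib$predictor[seq_len(min(config$top_k,
                                             nrow(avg_contrib)))]
    inter <- NULL
    if (length(top) >= 2) {
      pairs <- utils::combn(top, 2)
      score <- apply(pairs, 2, function(pr)
        mean(vapply(fits, function(m)
          interaction_size(m, pr[1], pr[2],
                           grid_points = config$pd_grid_points), numeric(1))))
      inter <- data.frame(predictor_i = pairs[1, ], predictor_j = pairs[2, ],
                          score = score)
      inter <- inter[order(-inter$score), , drop = FALSE]
    }
    raster <- average_replicates(rasters)
    raster <- discretize_and_areas(raster, config$cell_area_ha)
    tss_mean <- list(
      t_max_tss = mean(vapply(tsss, `[[`, numeric(1), "t_max_tss")),
      max_tss = mean(vapply(tsss, `[[`, numeric(1), "max_tss")),
      t_p10 = mean(vapply(tsss, `[[`, numeric(1), "t_p10")),
      tss_p10 = mean(vapply(tsss, `[[`, numeric(1), "tss_p10")))
    list(scheme = "RDM", species = sp,
         a_k = pa_sets[[1]]$a_k, sum_weights = sum(pa_sets[[1]]$weights),
         models = fits, cv = cvm, tss = tss_mean, tss_replicates = tsss,
         contributions = avg_contrib,
         top_k = list(contributions =
                        avg_contrib[seq_along(top), , drop = FALSE],
                      interactions = inter),
         raster = raster,
         n_trees_used = vapply(fits, `[[`, integer(1), "n_trees_used"),
         bag_fraction = vapply(fits, function(m) m$params$bag_fraction,
                               numeric(1)))
  }
}

compare_all <- function(results, config) {
  rows <- list()
  for (sp in names(results)) {
    ok <- names(results[[sp]])[!vapply(results[[sp]],
                                       function(r) isTRUE(r$failed),
                                       logical(1))]
    if (length(ok) < 2) next
    prs <- utils::combn(ok, 2)
    for (j in seq_len(ncol(prs))) {
      a <- results[[sp]][[prs[1, j]]]; b <- results[[sp]][[prs[2, j]]]
      for (metric in c("auc", "deviance")) {
        sa <- if (metric == "auc") a$cv$per_fold_auc else a$cv$per_fold_deviance
        sb <- if (metric == "auc") b$cv$per_fold_auc else b$cv$per_fold_deviance
        cr <- tryCatch(compare_metric_samples(sa, sb, config$alpha),
                       error = function(e) NULL)
        if (is.null(cr)) next
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, metric = toupper(metric),
          scheme_a = prs[1, j], scheme_b = prs[2, j],
          mean_a = mean(sa), mean_b = mean(sb),
          shapiro_p_a = cr$normality_p[["a"]],
          shapiro_p_b = cr$normality_p[["b"]], levene_p = cr$levene_p,
          test_used = cr$test_used, statistic = cr$statistic,
          p_value = cr$p_value, significant = cr$significant)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Tabulate the fold-level metrics of a study report
#'
#' @param report a `study_report`.
#' @return data.frame: one row per species x scheme with mean/SE of the
#'   cross-validated AUC and deviance, the sample size behind them, selected
#'   tree counts and bag fraction, plus the background size `a_k`.
#' @export
cv_metrics_table <- function(report) {
  rows <- list()
  for (sp in names(report$results)) for (sc in names(report$results[[sp]])) {
    r <- report$results[[sp]][[sc]]
    if (isTRUE(r$failed)) next
    rows[[length(rows) + 1]] <- data.frame(
      species = sp, scheme = sc, n = r$cv$n,
      mean_auc = r$cv$mean_auc, se_auc = r$cv$se_auc,
      mean_deviance = r$cv$mean_deviance, se_deviance = r$cv$se_deviance,
      a_k = r$a_k, sum_weights = r$sum_weights,
      n_trees = paste(r$n_trees_used, collapse = "/"),
      bag_fraction = paste(r$bag_fraction, collapse = "/"))
  }
  do.call(rbind, rows)
}

write_study_report <- function(report, stack, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(cv_metrics_table(report), "cv_metrics.csv")
  wcsv(report$comparisons, "comparisons.csv")
  wcsv(report$moran, "moran.csv")
  write_occurrences(report$group, file.path(out_dir, "target_group.csv"))
  areas <- list(); tssr <- list(); contr <- list(); inter <- list()
  for (sp in names(report$results)) for (sc in names(report$results[[sp]])) {
    r <- report$results[[sp]][[sc]]
    if (isTRUE(r$failed)) next
    areas[[paste(sp, sc)]] <- cbind(species = sp, scheme = sc,
                                    r$raster$class_areas)
    tssr[[paste(sp, sc)]] <- data.frame(
      species = sp, scheme = sc,
      t_max_tss = r$tss$t_max_tss, max_tss = r$tss$max_tss,
      t_p10 = r$tss$t_p10, tss_p10 = r$tss$tss_p10)
    contr[[paste(sp, sc)]] <- cbind(species = sp, scheme = sc,
                                    r$contributions)
    if (!is.null(r$top_k$interactions) && nrow(r$top_k$interactions) > 0)
      inter[[paste(sp, sc)]] <- cbind(species = sp, scheme = sc,
                                      r$top_k$interactions)
    write_ascii_grid(r$raster,
                     file.path(out_dir, paste0("suitability_", sp, "_",
                                               sc, ".asc")))
  }
  wcsv(do.call(rbind, areas), "class_areas.csv")
  wcsv(do.call(rbind, tssr), "tss.csv")
  wcsv(do.call(rbind, contr), "contributions.csv")
  wcsv(do.call(rbind, inter), "interactions.csv")
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  tab <- cv_metrics_table(x)
  if (!is.null(tab)) print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
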