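#' Pseudo-absence sets
#'
#' Container for artificial absence points with per-point weights, tagged by
#' generation scheme (`"UTGB"`, `"WTGB"` or `"RDM"`) and, for random
#' replicates, by replicate id.
#'
#' @param focal_species focal species label.
#' @param scheme generation scheme.
#' @param points data.frame with `x`, `y`.
#' @param weights positive per-point weights.
#' @param replicate_id integer replicate index (RDM) or `NULL`.
#' @param seed seed used for the draw, or `NULL` for deterministic schemes.
#' @return object of class `pseudo_absence_set` with point count `a_k`.
#' @export
pseudo_absence_set <- function(focal_species, scheme, points, weights,
                               replicate_id = NULL, seed = NULL) {
  scheme <- match.arg(scheme, c("UTGB", "WTGB", "RDM"))
  if (length(weights) != nrow(points))
    stop_bad_arg("one weight per point required")
  if (any(weights <= 0)) stop_bad_arg("all weights must be positive")
  structure(list(focal_species = focal_species, scheme = scheme,
                 points = points[, c("x", "y"), drop = FALSE],
                 weights = weights, a_k = nrow(points),
                 replicate_id = replicate_id, seed = seed),
            class = "pseudo_absence_set")
}

#' @export
print.pseudo_absence_set <- function(x, ...) {
  cat(sprintf("<pseudo_absence_set> %s for '%s': a_k = %d, sum(w) = %g%s\n",
              x$scheme, x$focal_species, x$a_k, sum(x$weights),
              if (!is.null(x$replicate_id))
                sprintf(" (replicate %d)", x$replicate_id) else ""))
  invisible(x)
}

# other-species points of the group, minus those sharing a cell (or exact
# coordinates when cell_size is NULL) with a focal presence
tg_background_points <- function(group, focal, cell_size = NULL,
                                 origin = c(0, 0)) {
  if (!inherits(group, "target_group")) stop_bad_arg("`group` must be a target_group")
  if (length(group$species_sets) < 2)
    stop_bad_arg("target group requires >= 2 species")
  if (!focal %in% names(group$species_sets))
    stop_bad_arg("focal species '", focal, "' not in the target group")
  others <- do.call(rbind, group$species_sets[setdiff(names(group$species_sets),
                                                      focal)])
  fp <- group$species_sets[[focal]]
  key <- function(px, py) {
    if (is.null(cell_size)) paste(px, py)
    else paste(floor((px - origin[1]) / cell_size),
               floor((py - origin[2]) / cell_size))
  }
  keep <- !(key(others$x, others$y) %in% key(fp$x, fp$y))
  others[keep, , drop = FALSE]
}

#' Unweighted target-group background (UTGB)
#'
#' Pseudo-absences for the focal species are the presence points of the other
#' species in the target group, excluding any point that shares a raster cell
#' with a focal presence ("non-overlapping" background). When no coincident
#' cells exist, the count identity `a_k = D - p_k` holds exactly. All weights
#' are 1.
#'
#' @param group a [target_group()].
#' @param focal focal species label (must be in the group).
#' @param cell_size,origin optional grid used to decide cell coincidence;
#'   with the default `cell_size = NULL`, exact coordinate equality is used
#'   (appropriate when all points are snapped to cell centres).
#' @return a [pseudo_absence_set()] with scheme `"UTGB"`.
#' @export
generate_utgb <- function(group, focal, cell_size = NULL, origin = c(0, 0)) {
  bg <- tg_background_points(group, focal, cell_size, origin)
  if (nrow(bg) == 0)
    warning("all other-species points coincide with focal presences; ",
            "empty background for '", focal, "'", call. = FALSE)
  pseudo_absence_set(focal, "UTGB", bg, weights = rep(1, nrow(bg)))
}

#' Weighted target-group background (WTGB)
#'
#' Same points as [generate_utgb()], but each pseudo-absence carries the
#' weight `W_ik = p_k / a_k`, so that the summed weight over pseudo-absences
#' equals the summed (unit) weight over the focal presences:
#' `sum(W_ik) = p_k`.
#'
#' @inheritParams generate_utgb
#' @return a [pseudo_absence_set()] with scheme `"WTGB"`.
#' @export
generate_wtgb <- function(group, focal, cell_size = NULL, origin = c(0, 0)) {
  bg <- tg_background_points(group, focal, cell_size, origin)
  if (nrow(bg) == 0)
    stop_bad_arg("cannot weight an empty background (focal '", focal, "')")
  p_k <- nrow(group$species_sets[[focal]])
  pseudo_absence_set(focal, "WTGB", bg,
                     weights = rep(p_k / nrow(bg), nrow(bg)))
}

#' Random pseudo-absence replicates (RDM)
#'
#' Each replicate draws `p_k` distinct grid cells uniformly at random from
#' the whole study area excluding the focal presence cells, matching the
#' presence count. Replicates use deterministic sub-seeds
#' `seed + replicate index`, and all weights are 1.
#'
#' @param stack an [env_stack()] defining the study-area grid.
#' @param focal_presences occurrence data.frame of the focal species.
#' @param n_replicates number of replicates (default 4).
#' @param seed master seed.
#' @return list of [pseudo_absence_set()]s with scheme `"RDM"`.
#' @export
generate_rdm <- function(stack, focal_presences, n_replicates = 4, seed = 1) {
  stopifnot(inherits(stack, "env_stack"))
  if (!is_count(n_replicates) || n_replicates < 1)
    stop_bad_arg("`n_replicates` must be an integer >= 1")
  p_k <- nrow(focal_presences)
  if (p_k < 1) stop_bad_arg("focal species has no presences")
  rc <- coords_to_cell(stack, focal_presences$x, focal_presences$y)
  presence_cells <- unique((rc[, 2] - 1L) * stack$n_rows + rc[, 1])
  all_cells <- seq_len(stack$n_rows * stack$n_cols)
  candidates <- setdiff(all_cells, presence_cells)
  if (length(candidates) < p_k)
    stop_bad_arg("cannot draw ", p_k, " random pseudo-absences: required ",
                 p_k, ", available non-presence cells ", length(candidates))
  sp <- if ("species" %in% names(focal_presences))
    focal_presences$species[1] else "focal"
  lapply(seq_len(n_replicates), function(r) {
    cells <- with_seed(seed + r, {
      if (length(candidates) == p_k) candidates
      else sample(candidates, p_k)
    })
    row <- (cells - 1L) %% stack$n_rows + 1L
    col <- (cells - 1L) %/% stack$n_rows + 1L
    pts <- data.frame(x = stack$origin[1] + (col - 0.5) * stack$cell_size,
                      y = stack$origin[2] + (row - 0.5) * stack$cell_size)
    pseudo_absence_set(sp, "RDM", pts, weights = rep(1, p_k),
                       replicate_id = r, seed = seed + r)
  })
}

#' Assemble a presence/pseudo-absence training table
#'
#' Binds focal presences (label 1, weight 1) with a pseudo-absence set
#' (label 0, the set's weights) and extracts the environmental predictors at
#' every point.
#'
#' @param stack an [env_stack()].
#' @param presences occurrence data.frame of the focal species.
#' @param pa_set a [pseudo_absence_set()].
#' @return list with predictor matrix `X`, binary `y` and weights `w`.
#' @export
build_training_data <- function(stack, presences, pa_set) {
  stopifnot(inherits(pa_set, "pseudo_absence_set"))
  pts <- rbind(presences[, c("x", "y")], pa_set$points)
  X <- extract_env(stack, pts)
  list(X = X,
       y = c(rep(1, nrow(presences)), rep(0, pa_set$a_k)),
       w = c(rep(1, nrow(presences)), pa_set$weights))
}

#' Write pseudo-absence sets as CSV
#'
#' Columns `species`, `x`, `y`, `weight`, `scheme`, `replicate`, compatible
#' with [read_occurrences()].
#'
#' @param sets a [pseudo_absence_set()] or list of them.
#' @param path output file.
#' @export
write_pseudo_absences <- function(sets, path) {
  if (inherits(sets, "pseudo_absence_set")) sets <- list(sets)
  rows <- lapply(sets, function(s)
    data.frame(species = s$focal_species, x = s$points$x, y = s$points$y,
               weight = s$weights, scheme = s$scheme,
               replicate = s$replicate_id %||% NA_integer_))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
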