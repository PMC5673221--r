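#' Project a fitted model over an environmental stack
#'
#' Predicts the relative likelihood of occurrence for every grid cell. Cells
#' with a missing value in any training predictor are flagged no-data (NA)
#' and excluded from subsequent class areas.
#'
#' @param model a `brt_model`.
#' @param stack an [env_stack()] containing all training predictors.
#' @param species,scheme,replicate_id labels carried into the raster.
#' @return object of class `suitability_raster`: probability matrix
#'   `values` in (0, 1) plus georeferencing and labels.
#' @export
project <- function(model, stack, species = NULL, scheme = NULL,
                    replicate_id = NULL) {
  stopifnot(inherits(model, "brt_model"), inherits(stack, "env_stack"))
  missing <- setdiff(model$var_names, stack$layer_names)
  if (length(missing) > 0)
    stop_bad_arg("stack lacks layer(s): ", paste(missing, collapse = ", "))
  X <- vapply(model$var_names, function(nm) as.vector(stack$layers[[nm]]),
              numeric(stack$n_rows * stack$n_cols))
  X <- matrix(X, ncol = length(model$var_names),
              dimnames = list(NULL, model$var_names))
  ok <- stats::complete.cases(X)
  vals <- rep(NA_real_, nrow(X))
  if (any(ok))
    vals[ok] <- predict(model, X[ok, , drop = FALSE])
  structure(list(values = matrix(vals, stack$n_rows, stack$n_cols),
                 cell_size = stack$cell_size, origin = stack$origin,
                 species = species, scheme = scheme,
                 replicate_id = replicate_id),
            class = "suitability_raster")
}

#' Average suitability rasters cell by cell
#'
#' Arithmetic mean of two or more rasters on identical grids (the treatment
#' of random-replicate projections before mapping); a no-data cell in any
#' input stays no-data in the mean.
#'
#' @param rasters list of at least two `suitability_raster`s.
#' @return a `suitability_raster` (replicate_id dropped).
#' @export
average_replicates <- function(rasters) {
  if (length(rasters) < 2) stop_bad_arg("need >= 2 rasters to average")
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        !isTRUE(all.equal(r$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(r$origin, ref$origin)))
      stop_bad_arg("rasters are on different grids")
  }
  acc <- Reduce(`+`, lapply(rasters, function(r) r$values))
  out <- ref
  out$values <- acc / length(rasters)
  out$replicate_id <- NULL
  out
}

#' Discretize a suitability raster into five likelihood classes with areas
#'
#' Classes cover \[0, 0.2), \[0.2, 0.4), \[0.4, 0.6), \[0.6, 0.8) and
#' \[0.8, 1.0\] (half-open below, top class closed). Class areas are cell
#' counts times `cell_area_ha`; percentages are taken over mapped (non-NA)
#' cells and sum to 100.
#'
#' @param raster a `suitability_raster`.
#' @param cell_area_ha area of one cell in hectares (> 0); defaults to
#'   `cell_size^2` (i.e. map units are hectometres).
#' @return the raster with `class_grid` (1-5, NA for no-data) and
#'   `class_areas` (data.frame `class`, `lower`, `upper`, `cells`,
#'   `extent_ha`, `percent`).
#' @export
discretize_and_areas <- function(raster, cell_area_ha = NULL) {
  stopifnot(inherits(raster, "suitability_raster"))
  if (is.null(cell_area_ha)) cell_area_ha <- raster$cell_size^2
  if (cell_area_ha <= 0) stop_bad_arg("`cell_area_ha` must be > 0")
  v <- raster$values
  cls <- matrix(findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1L,
                nrow(v), ncol(v))
  cls[is.na(v)] <- NA_integer_
  n_mapped <- sum(!is.na(cls))
  counts <- vapply(1:5, function(k) sum(cls == k, na.rm = TRUE), integer(1))
  areas <- data.frame(class = 1:5,
                      lower = c(0, 0.2, 0.4, 0.6, 0.8),
                      upper = c(0.2, 0.4, 0.6, 0.8, 1.0),
                      cells = counts,
                      extent_ha = counts * cell_area_ha,
                      percent = 100 * counts / n_mapped)
  out <- raster
  out$class_grid <- cls
  out$class_areas <- areas
  out
}

#' @export
print.suitability_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<suitability_raster>%s%s %d x %d cells, values %.3f-%.3f\n",
              if (!is.null(x$species)) paste0(" ", x$species) else "",
              if (!is.null(x$scheme)) paste0(" (", x$scheme, ")") else "",
              nrow(x$values), ncol(x$values), rng[1], rng[2]))
  if (!is.null(x$class_areas)) {
    cat("  class areas (ha / %):\n")
    a <- x$class_areas
    for (i in 1:5)
      cat(sprintf("    %.1f-%.1f  %10.1f  %6.2f%%\n", a$lower[i], a$upper[i],
                  a$extent_ha[i], a$percent[i]))
  }
  invisible(x)
}
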