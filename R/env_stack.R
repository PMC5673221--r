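#' Environmental layer stacks
#'
#' An `env_stack` holds a set of gridded environmental predictors sharing one
#' georeferencing: a list of `n_rows x n_cols` matrices (row 1 is the
#' southernmost row, column 1 the westernmost column), a linear `cell_size`
#' in map units and the coordinates of the grid's lower-left corner. Cell
#' centres are at `origin + (index - 0.5) * cell_size`.
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @param cell_size linear cell size in map units (> 0).
#' @param origin numeric length-2, lower-left corner of the grid.
#' @param units optional named character vector of per-layer units.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, cell_size = 1, origin = c(0, 0), units = NULL) {
  if (!is.list(layers) || length(layers) == 0 || is.null(names(layers)) ||
      any(names(layers) == ""))
    stop_bad_arg("`layers` must be a non-empty named list of matrices")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_bad_arg("all layers must share the same dimensions")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop_bad_arg("`cell_size` must be a positive scalar")
  structure(list(
    layers = layers,
    layer_names = names(layers),
    n_rows = dims[1, 1],
    n_cols = dims[2, 1],
    cell_size = cell_size,
    origin = as.numeric(origin[1:2]),
    units = units
  ), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers, %d x %d cells (cell size %g)\n",
              length(x$layers), x$n_rows, x$n_cols, x$cell_size))
  cat("  layers:", paste(x$layer_names, collapse = ", "), "\n")
  invisible(x)
}

# Gaussian smoothing of a matrix (separable convolution, reflected edges).
smooth_field <- function(m, radius = 3) {
  if (radius <= 0) return(m)
  half <- max(1L, ceiling(2 * radius))
  kern <- stats::dnorm(seq(-half, half), sd = radius)
  kern <- kern / sum(kern)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1, n)]))
    out <- stats::filter(xp, kern, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' Generate a synthetic stack of correlated, spatially autocorrelated layers
#'
#' Layers are built as a mix of one shared latent field and a layer-specific
#' field (mixing weight `sqrt(correlation)`), each being low-pass-filtered
#' white noise plus a planar gradient of random orientation, then
#' standardized. The last two layers are transformed into topography:
#' `SLOPE` (non-negative, degrees) and `ASPECT` (wrapped to \[0, 360)
#' degrees); the layer before them is named `ALT` and any remaining layers
#' `BIO1`, `BIO2`, ... in imitation of a bioclimatic predictor set. Because
#' the topographic transforms are non-linear, the requested correlation level
#' applies to the non-topographic layers.
#'
#' @param n_rows,n_cols grid dimensions (each >= 10).
#' @param n_layers number of layers (>= 3).
#' @param correlation target pairwise correlation of the untransformed
#'   layers, in \[0, 1).
#' @param seed integer seed; identical arguments give bit-identical stacks.
#' @param cell_size,origin georeferencing, see [env_stack()].
#' @param smoothing_radius Gaussian sd (in cells) of the low-pass filter.
#' @return an [env_stack()].
#' @export
make_env_stack <- function(n_rows, n_cols, n_layers, correlation = 0.5,
                           seed = 1, cell_size = 1, origin = c(0, 0),
                           smoothing_radius = 2) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 10 || n_cols < 10)
    stop_bad_arg("`n_rows` and `n_cols` must be integers >= 10")
  if (!is_count(n_layers) || n_layers < 3)
    stop_bad_arg("`n_layers` must be an integer >= 3")
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1)
    stop_bad_arg("`correlation` must lie in [0, 1)")

  with_seed(seed, {
    rows <- matrix(seq_len(n_rows) / n_rows, n_rows, n_cols)
    cols <- matrix(rep(seq_len(n_cols) / n_cols, each = n_rows), n_rows, n_cols)
    gen_field <- function() {
      z <- smooth_field(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                        smoothing_radius)
      ang <- stats::runif(1, 0, 2 * pi)
      g <- cos(ang) * rows + sin(ang) * cols
      z <- scale_mat(z) + 0.35 * scale_mat(g)
      scale_mat(z)
    }
    shared <- gen_field()
    a <- sqrt(correlation)
    b <- sqrt(1 - correlation)
    raw <- lapply(seq_len(n_layers), function(i) {
      scale_mat(a * shared + b * gen_field())
    })

    nm <- layer_name_set(n_layers)
    layers <- stats::setNames(raw, nm)
    layers[["SLOPE"]] <- abs(layers[["SLOPE"]]) * 10          # degrees, >= 0
    layers[["ASPECT"]] <- (layers[["ASPECT"]] * 110) %% 360   # degrees [0,360)
    units <- stats::setNames(rep("index", n_layers), nm)
    units[c("SLOPE", "ASPECT")] <- "degrees"
    units["ALT"] <- "m"
    env_stack(layers, cell_size = cell_size, origin = origin, units = units)
  })
}

layer_name_set <- function(n_layers) {
  if (n_layers == 3) c("ALT", "SLOPE", "ASPECT")
  else c(paste0("BIO", seq_len(n_layers - 3)), "ALT", "SLOPE", "ASPECT")
}

scale_mat <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Convert a stack to a per-cell predictor table
#'
#' @param x an [env_stack()].
#' @param row.names,optional unused (S3 signature).
#' @param ... unused.
#' @return a data.frame with one row per grid cell: `x`, `y` cell-centre
#'   coordinates, `cell` linear index, and one column per layer.
#' @export
as.data.frame.env_stack <- function(x, row.names = NULL, optional = FALSE, ...) {
  rc <- expand.grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols))
  out <- data.frame(
    cell = seq_len(x$n_rows * x$n_cols),
    x = x$origin[1] + (rc$col - 0.5) * x$cell_size,
    y = x$origin[2] + (rc$row - 0.5) * x$cell_size
  )
  for (nm in x$layer_names) out[[nm]] <- as.vector(x$layers[[nm]])
  out
}

# cell-centre coordinates -> (row, col); errors if off-grid
coords_to_cell <- function(stack, x, y) {
  col <- floor((x - stack$origin[1]) / stack$cell_size) + 1L
  row <- floor((y - stack$origin[2]) / stack$cell_size) + 1L
  bad <- col < 1 | col > stack$n_cols | row < 1 | row > stack$n_rows
  if (any(bad))
    stop_bad_arg(sum(bad), " point(s) fall outside the stack extent")
  cbind(row = row, col = col)
}

# environmental values at point locations, as a predictor matrix
extract_env <- function(stack, points) {
  rc <- coords_to_cell(stack, points$x, points$y)
  out <- vapply(stack$layer_names,
                function(nm) stack$layers[[nm]][cbind(rc[, 1], rc[, 2])],
                numeric(nrow(points)))
  out <- matrix(out, nrow = nrow(points),
                dimnames = list(NULL, stack$layer_names))
  out
}
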