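#' Read occurrence tables
#'
#' Reads a CSV with columns `species`, `x`, `y` (decimal coordinates) and
#' splits it into one occurrence set per species, preserving row order.
#'
#' @param path CSV file path.
#' @return named list of occurrence data.frames (one per distinct species
#'   label, in order of first appearance).
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  for (col in c("species", "x", "y"))
    if (!col %in% names(raw))
      stop_bad_arg("missing column `", col, "` in ", path)
  if (nrow(raw) == 0) return(stats::setNames(list(), character(0)))
  xs <- suppressWarnings(as.numeric(raw$x))
  ys <- suppressWarnings(as.numeric(raw$y))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad) > 0)
    stop_bad_arg("non-numeric coordinate at row ", bad[1], " of ", path)
  df <- data.frame(species = raw$species, x = xs, y = ys)
  split(df, factor(df$species, levels = unique(df$species)))
}

#' Write occurrence points (or a whole target group) as CSV
#'
#' @param x occurrence data.frame (`species`, `x`, `y`) or a
#'   [target_group()].
#' @param path output file.
#' @export
write_occurrences <- function(x, path) {
  if (inherits(x, "target_group")) x <- do.call(rbind, x$species_sets)
  utils::write.csv(x[, c("species", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Aggregate points onto a regular grid of counts
#'
#' Each point is assigned to exactly one cell by the half-open convention
#' `floor((coord - origin) / cell_size)`: a point exactly on a boundary
#' belongs to the higher-index cell. The grid extends over the bounding box
#' of the points, so no point is lost.
#'
#' @param points occurrence data.frame with `x`, `y`.
#' @param cell_size cell size in map units (> 0).
#' @param origin grid origin (any cell corner), default `c(0, 0)`.
#' @return object of class `count_grid`: list with the `counts` matrix
#'   (rows = south to north), `cell_size` and the `origin` of its lower-left
#'   cell corner.
#' @export
grid_aggregate <- function(points, cell_size, origin = c(0, 0)) {
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop_bad_arg("`cell_size` must be > 0")
  if (nrow(points) == 0) stop_bad_arg("no points to aggregate")
  ix <- floor((points$x - origin[1]) / cell_size)
  iy <- floor((points$y - origin[2]) / cell_size)
  cx <- ix - min(ix) + 1L
  cy <- iy - min(iy) + 1L
  counts <- matrix(0L, max(cy), max(cx))
  for (i in seq_along(cx))
    counts[cy[i], cx[i]] <- counts[cy[i], cx[i]] + 1L
  structure(list(counts = counts, cell_size = cell_size,
                 origin = c(origin[1] + min(ix) * cell_size,
                            origin[2] + min(iy) * cell_size)),
            class = "count_grid")
}

# contiguity / inverse-distance spatial weights for an R x C lattice
lattice_weights <- function(n_rows, n_cols,
                            scheme = c("queen", "rook", "inverse_distance")) {
  scheme <- match.arg(scheme)
  n <- n_rows * n_cols
  idx <- function(r, c) (c - 1L) * n_rows + r
  W <- matrix(0, n, n)
  if (scheme == "inverse_distance") {
    rc <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
    d <- as.matrix(stats::dist(rc[, c("c", "r")]))
    W <- ifelse(d > 0, 1 / d, 0)
  } else {
    offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    if (scheme == "queen")
      offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
      rr <- r + offs[, 1]; cc <- c + offs[, 2]
      keep <- rr >= 1 & rr <= n_rows & cc >= 1 & cc <= n_cols
      W[idx(r, c), idx(rr[keep], cc[keep])] <- 1
    }
  }
  W
}

#' Global Moran's I on a count grid
#'
#' Computes Moran's index
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over the cells of a lattice, with binary queen (default) or rook
#' contiguity weights, or inverse-distance weights. Significance uses the
#' randomization null: `E[I] = -1/(n-1)` with the standard randomization
#' variance (kurtosis-corrected), a normal deviate `z` and a two-sided
#' p-value. A permutation p-value (`permutations` random relabelings of the
#' cell values) can be requested as a check on the analytic null.
#'
#' @param grid a [grid_aggregate()] result or a plain numeric matrix.
#' @param weight_scheme `"queen"`, `"rook"` or `"inverse_distance"`.
#' @param permutations number of random permutations (0 = analytic only).
#' @param seed seed for the permutation draw.
#' @return object of class `moran_result`: `I`, `expected`, `sd`, `z_score`,
#'   `p_value`, `n_cells`, `weight_scheme`, and `p_permutation` when
#'   requested.
#' @export
morans_i <- function(grid, weight_scheme = c("queen", "rook", "inverse_distance"),
                     permutations = 0, seed = 1) {
  weight_scheme <- match.arg(weight_scheme)
  m <- if (inherits(grid, "count_grid")) grid$counts else grid
  stopifnot(is.matrix(m))
  x <- as.numeric(m)
  n <- length(x)
  if (n < 2) stop_bad_arg("Moran's I needs at least 2 cells")
  if (stats::var(x) == 0)
    stop_bad_arg("Moran's I undefined for constant field")
  W <- lattice_weights(nrow(m), ncol(m), weight_scheme)

  I_of <- function(v) {
    z <- v - mean(v)
    (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  }
  I <- I_of(x)

  z <- x - mean(x)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  EI <- -1 / (n - 1)
  A <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2)
  B <- b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  VI <- (A - B) / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zs <- (I - EI) / sqrt(VI)
  p <- 2 * stats::pnorm(-abs(zs))

  out <- list(I = I, expected = EI, sd = sqrt(VI), z_score = zs, p_value = p,
              n_cells = n, weight_scheme = weight_scheme)
  if (permutations > 0) {
    Iperm <- with_seed(seed,
                       vapply(seq_len(permutations),
                              function(i) I_of(sample(x)), numeric(1)))
    r <- sum(abs(Iperm - EI) >= abs(I - EI))
    out$p_permutation <- (r + 1) / (permutations + 1)
  }
  structure(out, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f, z-score = %.3f, p-value = %.4f (%s, n = %d)\n",
              x$I, x$z_score, x$p_value, x$weight_scheme, x$n_cells))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p-value = %.4f\n", x$p_permutation))
  invisible(x)
}
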