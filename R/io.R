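#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows from north to south). Accepts a
#' bare matrix (unit cell, origin 0,0), a `suitability_raster`, a
#' `count_grid`, or one named layer of an [env_stack()].
#'
#' @param x the grid to write (see above).
#' @param path output file.
#' @param layer layer name, required when `x` is an `env_stack`.
#' @param nodata no-data sentinel written for NA cells.
#' @export
write_ascii_grid <- function(x, path, layer = NULL, nodata = -9999) {
  if (inherits(x, "env_stack")) {
    if (is.null(layer)) stop_bad_arg("`layer` required for an env_stack")
    if (!layer %in% x$layer_names) stop_bad_arg("no layer named ", layer)
    m <- x$layers[[layer]]; cs <- x$cell_size; or <- x$origin
  } else if (inherits(x, "suitability_raster")) {
    m <- x$values; cs <- x$cell_size; or <- x$origin
  } else if (inherits(x, "count_grid")) {
    m <- x$counts; cs <- x$cell_size; or <- x$origin
  } else {
    m <- x
    cs <- attr(x, "cell_size") %||% 1
    or <- attr(x, "origin") %||% c(0, 0)
  }
  stopifnot(is.matrix(m))
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", format(or[1], digits = 15)),
               paste("yllcorner", format(or[2], digits = 15)),
               paste("cellsize", format(cs, digits = 15)),
               paste("NODATA_value", nodata)), con)
  for (r in rev(seq_len(nrow(m))))   # north to south
    writeLines(paste(format(m[r, ], digits = 15, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return a matrix (row 1 = southernmost row) with attributes `cell_size`
#'   and `origin`; no-data cells become NA.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop_bad_arg("malformed ASCII grid: missing ", k)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop_bad_arg("cell count does not match header")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "cell_size") <- hdr$cellsize
  attr(m, "origin") <- c(hdr$xllcorner, hdr$yllcorner)
  m
}

#' Serialize a fitted ensemble to JSON
#'
#' Documented schema: `intercept`, `params`, `n_trees_used`, `var_names`,
#' and `trees` as arrays of node records (`var` as 1-based predictor index
#' or 0 for terminals, `split`, `left`, `right` as 1-based node indices or
#' 0, `gain`, `value`). Training data are not serialized; a deserialized
#' model predicts but cannot recompute partial dependence.
#'
#' @param model a `brt_model`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
brt_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "brt_model"))
  tree_rec <- function(tr) {
    data.frame(var = as.integer(tr[, 1]) + 1L, split = tr[, 2],
               left = as.integer(tr[, 3]) + 1L,
               right = as.integer(tr[, 4]) + 1L,
               gain = tr[, 5], value = tr[, 6])
  }
  obj <- list(intercept = model$intercept,
              params = unclass(model$params),
              n_trees_used = model$n_trees_used,
              var_names = model$var_names,
              trees = lapply(model$trees, tree_rec))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a JSON ensemble written by [brt_to_json()]
#'
#' @param path file or JSON string.
#' @return a `brt_model` usable with [predict.brt_model()].
#' @export
brt_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  trees <- lapply(obj$trees, function(df) {
    cbind(df$var - 1, df$split, df$left - 1, df$right - 1, df$gain, df$value)
  })
  params <- do.call(brt_params, obj$params[names(obj$params) %in%
                                             names(formals(brt_params))])
  structure(list(intercept = obj$intercept, trees = trees, params = params,
                 n_trees_used = obj$n_trees_used,
                 var_names = obj$var_names,
                 X = NULL, y = NULL, w = NULL,
                 training_summary = list()),
            class = "brt_model")
}
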