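#' Virtual species with a known suitability function
#'
#' A virtual species is defined by a linear-logistic response to the stack's
#' predictors: on the logit scale, suitability is
#' `intercept + sum(coefficients * x) + sum(interaction coefficients * x_i * x_j)`.
#' Sampling presences from the resulting probability surface produces
#' occurrence data whose true environmental drivers are known, so that
#' variable-selection and interaction-recovery behaviour of downstream models
#' can be checked.
#'
#' @param name species label.
#' @param coefficients named numeric vector of per-predictor logit-scale
#'   coefficients; at least one must be non-zero.
#' @param n_presences target number of presence points (>= 1).
#' @param interaction_terms list of `list(pred_a, pred_b, coefficient)`
#'   product terms.
#' @param intercept scalar logit-scale intercept.
#' @param seed optional integer seed used when sampling this species.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(name, coefficients, n_presences,
                            interaction_terms = list(), intercept = 0,
                            seed = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_bad_arg("`name` must be a non-empty string")
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      all(coefficients == 0))
    stop_bad_arg("`coefficients` must be a named numeric vector with at least ",
                 "one non-zero entry")
  if (!is_count(n_presences) || n_presences < 1)
    stop_bad_arg("`n_presences` must be an integer >= 1 (species '", name, "')")
  for (it in interaction_terms)
    if (length(it) != 3 || !is.numeric(it[[3]]))
      stop_bad_arg("each interaction term must be list(pred_a, pred_b, coef)")
  structure(list(name = name, coefficients = coefficients,
                 interaction_terms = interaction_terms,
                 intercept = intercept, n_presences = as.integer(n_presences),
                 seed = seed),
            class = "virtual_species")
}

#' Per-cell suitability of a virtual species over a stack
#'
#' @param stack an [env_stack()].
#' @param spec a [virtual_species()].
#' @return a matrix of probabilities in (0, 1) with the stack's dimensions,
#'   carrying the stack georeferencing as attributes.
#' @export
suitability_surface <- function(stack, spec) {
  stopifnot(inherits(stack, "env_stack"), inherits(spec, "virtual_species"))
  used <- union(names(spec$coefficients),
                unlist(lapply(spec$interaction_terms, function(it) c(it[[1]], it[[2]]))))
  missing <- setdiff(used, stack$layer_names)
  if (length(missing) > 0)
    stop_bad_arg("predictor(s) not in stack: ", paste(missing, collapse = ", "))
  lp <- matrix(spec$intercept, stack$n_rows, stack$n_cols)
  for (nm in names(spec$coefficients))
    lp <- lp + spec$coefficients[[nm]] * stack$layers[[nm]]
  for (it in spec$interaction_terms)
    lp <- lp + it[[3]] * stack$layers[[it[[1]]]] * stack$layers[[it[[2]]]]
  out <- stats::plogis(lp)
  attr(out, "cell_size") <- stack$cell_size
  attr(out, "origin") <- stack$origin
  out
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` distinct cells without replacement with selection probability
#' proportional to suitability, and returns their cell-centre coordinates.
#'
#' @param suitability probability matrix, e.g. from [suitability_surface()];
#'   georeferencing is read from its attributes (cell size 1, origin (0,0)
#'   when absent).
#' @param n number of presences; must not exceed the number of cells with
#'   positive suitability.
#' @param seed integer seed.
#' @param species label attached to the returned points.
#' @param exclude optional logical matrix marking cells that must not be
#'   selected (used to keep species on distinct cells).
#' @return a data.frame with columns `species`, `x`, `y`.
#' @export
sample_presences <- function(suitability, n, seed = 1, species = "sp",
                             exclude = NULL) {
  stopifnot(is.matrix(suitability))
  cs <- attr(suitability, "cell_size") %||% 1
  or <- attr(suitability, "origin") %||% c(0, 0)
  ok <- suitability > 0
  if (!is.null(exclude)) ok <- ok & !exclude
  avail <- which(ok)
  if (!is_count(n) || n < 1)
    stop_bad_arg("`n` must be a positive integer")
  if (n > length(avail))
    stop_bad_arg("requested ", n, " presences but only ", length(avail),
                 " cells have positive suitability")
  idx <- with_seed(seed, {
    if (n == length(avail)) avail
    else avail[sample.int(length(avail), n, prob = suitability[avail])]
  })
  rc <- arrayInd(idx, dim(suitability))
  data.frame(species = species,
             x = or[1] + (rc[, 2] - 0.5) * cs,
             y = or[2] + (rc[, 1] - 0.5) * cs)
}

#' Assemble a multi-species target group
#'
#' Samples each species' presences from its own suitability surface. By
#' default species occupy distinct cells (each species' surface is masked by
#' the cells already taken), so that the pooled group places its `D` records
#' on `D` distinct cells and the unweighted target-group background count
#' identity `a_k = D - p_k` holds exactly.
#'
#' @param stack an [env_stack()].
#' @param specs list of at least two [virtual_species()] with unique names.
#' @param seed master seed; species `i` uses `spec$seed` when set, else
#'   `seed + i`.
#' @param distinct_cells keep species on disjoint cells (default `TRUE`).
#' @return an object of class `target_group`: a list with `species_sets`
#'   (named list of occurrence data.frames) and the total record count `D`.
#' @export
make_target_group <- function(stack, specs, seed = 1, distinct_cells = TRUE) {
  stopifnot(inherits(stack, "env_stack"))
  if (length(specs) < 2)
    stop_bad_arg("a target group requires at least 2 species")
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop_bad_arg("duplicate species names: ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", "))
  occupied <- matrix(FALSE, stack$n_rows, stack$n_cols)
  sets <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    suit <- suitability_surface(stack, sp)
    pts <- sample_presences(suit, sp$n_presences,
                            seed = sp$seed %||% (seed + i),
                            species = sp$name,
                            exclude = if (distinct_cells) occupied else NULL)
    if (distinct_cells) {
      rc <- coords_to_cell(stack, pts$x, pts$y)
      occupied[cbind(rc[, 1], rc[, 2])] <- TRUE
    }
    sets[[i]] <- pts
  }
  names(sets) <- nms
  target_group(sets)
}

#' Construct a target group from occurrence sets
#'
#' @param species_sets named list of occurrence data.frames (columns
#'   `species`, `x`, `y`), one per species.
#' @return a `target_group` with total record count `D = sum(p_k)`.
#' @export
target_group <- function(species_sets) {
  if (is.null(names(species_sets)) || anyDuplicated(names(species_sets)))
    stop_bad_arg("`species_sets` must be a named list with unique names")
  for (s in species_sets)
    if (!all(c("x", "y") %in% names(s)))
      stop_bad_arg("each occurrence set needs `x` and `y` columns")
  structure(list(species_sets = species_sets,
                 D = sum(vapply(species_sets, nrow, integer(1)))),
            class = "target_group")
}

#' @export
print.target_group <- function(x, ...) {
  cat(sprintf("<target_group> %d species, D = %d records\n",
              length(x$species_sets), x$D))
  for (nm in names(x$species_sets))
    cat(sprintf("  %-28s p_k = %d\n", nm, nrow(x$species_sets[[nm]])))
  invisible(x)
}
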