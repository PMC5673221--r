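# internal helpers

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded fits do not disturb an enclosing simulation.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
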