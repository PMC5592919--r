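# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` means "use the current stream as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

# Scalar checks used by constructors and operation preconditions.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_input(sprintf("`%s` must be > %s", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    stop_input(sprintf("`%s` must be >= %s", name, format(lower)))
  }
  if (x > upper) {
    stop_input(sprintf("`%s` must be <= %s", name, format(upper)))
  }
  invisible(x)
}
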