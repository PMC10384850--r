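#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp median sd quantile predict setNames aggregate na.omit
#' @importFrom graphics hist
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All exported stochastic functions
# take an explicit seed and route their randomness through this helper, so
# nothing in the package mutates global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used across modules
assert_scalar_in <- function(x, name, lo, hi, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && abs(x - round(x)) < 1e-8
  if (!ok) stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(round(x)))
}
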