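# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_tc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tc("'%s' must be a single finite number", name)
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) stop_tc("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

# Deterministic sub-seed derivation: every stochastic routine takes a `seed`
# and derives child seeds for replicates/timepoints so that the same top-level
# seed reproduces byte-identical data. Kept below 2^31 - 1.
#' @noRd
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 12345 + 1) %% 2147483647
  as.integer(max(1, s))
}

#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# geometric mean of two positive lengths; used for the per-adenosine scaling
# of pairwise exponential coefficients
#' @noRd
geo_mean2 <- function(a, b) sqrt(a * b)
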