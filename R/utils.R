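# Internal helpers shared across modules.

# Standardize a vector to sample mean 0, sd 1 over its non-missing entries.
# Constant or all-missing input is an error unless allow_constant, in which
# case the centred vector is returned (all zeros).
zscore <- function(x, allow_constant = FALSE) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to standardize")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (s < .Machine$double.eps) {
    if (allow_constant) return(x - m)
    stop("cannot standardize a constant vector")
  }
  (x - m) / s
}

# Run code with a temporarily fixed RNG state; the caller's stream is
# restored afterwards so simulations do not perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
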