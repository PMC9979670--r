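#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic, collision-avoiding scheme used to give each lesion, frame
#' or fold its own reproducible stream. Result stays below 2^31.
#'
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1009 + 17) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw one integer uniformly from [lo, hi]; safe when lo == hi (base sample()
# would treat a scalar as 1:n)
sample_range <- function(lo, hi) if (lo >= hi) as.integer(lo) else sample(lo:hi, 1L)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
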