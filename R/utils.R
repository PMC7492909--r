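# Internal helpers shared across the pipeline.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so identical seeds give bit-identical results.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483587)
}

#' Min-max scale an array to [0, 1]
#'
#' Scales all entries of `x` jointly to the unit interval and records the
#' constants needed to invert the transform. Used before crossentropy-based
#' reconstruction, which requires targets in \[0, 1\].
#'
#' @param x numeric array.
#' @return list with `data` (scaled array), `min`, `max`.
#' @keywords internal
minmax_scale <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < .Machine$double.eps) {
    scaled <- array(0, dim = dim(x) %||% length(x))
  } else {
    scaled <- (x - lo) / (hi - lo)
  }
  list(data = scaled, min = lo, max = hi)
}

minmax_invert <- function(x, lo, hi) x * (hi - lo) + lo

# Per-feature (column) min-max scaling of a flat feature matrix to [0, 1];
# constant columns map to 0. This is the conventional feature-matrix scaler;
# the joint variant above is used for image tensors, whose cells must keep
# their relative structure.
minmax_scale_cols <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  flat <- span < .Machine$double.eps
  span[flat] <- 1
  scaled <- sweep(sweep(x, 2, lo), 2, span, `/`)
  scaled[, flat] <- 0
  list(data = scaled, min = lo, max = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x == round(x)
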