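# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# A rectangle in sample-plane nm: c(xmin, xmax, ymin, ymax).
as_region <- function(region) {
  region <- as.numeric(region)
  if (length(region) != 4L || any(!is.finite(region)) ||
      region[2] <= region[1] || region[4] <= region[3])
    stop("region must be c(xmin, xmax, ymin, ymax) with positive extent")
  region
}

in_region <- function(x, y, region) {
  x >= region[1] & x <= region[2] & y >= region[3] & y <= region[4]
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a positive scalar", name))
}

# Recycle a per-axis parameter to length 2 (x, y).
per_axis <- function(x, name) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)))
    stop(sprintf("%s must be length 1 or 2 and finite", name))
  x
}
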