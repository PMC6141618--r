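#' Evenly spaced contour levels
#'
#' Divides the full range of a scan image evenly into `n_levels` contour
#' values: the first level is the image minimum, the last the maximum, with
#' constant spacing between.
#'
#' @param image Numeric matrix (or vector) of signal values.
#' @param n_levels Number of levels (>= 2).
#' @return A `contour_levels` object: list with `levels` (ascending numeric
#'   vector of length `n_levels`), `n_levels`, and `spacing`.
#' @export
compute_levels <- function(image, n_levels) {
  if (!is.numeric(image) || any(!is.finite(image)))
    stop("image must be finite numeric")
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2)
    stop("n_levels must be >= 2")
  n_levels <- as.integer(n_levels)
  lo <- min(image); hi <- max(image)
  if (hi - lo <= 0) stop("constant image: zero range, no contours possible")
  levels <- seq(lo, hi, length.out = n_levels)
  structure(list(levels = levels, n_levels = n_levels,
                 spacing = (hi - lo) / (n_levels - 1)),
            class = "contour_levels")
}

# Nudge levels into the open range of the image (a level exactly equal to
# the image min/max crosses no cell edge) and off exact node values (where
# marching squares degenerates and displaces the crossing). The relative
# nudge of 1e-9 of the range moves a contour by ~1e-7 nm on a 100 nm scan,
# far below pack quantization.
.interior_levels <- function(levels, image) {
  rng <- range(image)
  eps <- (rng[2] - rng[1]) * 1e-9
  adj <- clamp(levels, rng[1] + eps, rng[2] - eps)
  hit <- vapply(adj, function(l) any(image == l), logical(1))
  adj[hit] <- adj[hit] + eps
  adj
}

#' Extract sub-pixel iso-signal contours
#'
#' Marching-squares contour extraction with linear interpolation on pixel
#' edges (via [grDevices::contourLines()]), returning polylines in
#' sample-plane nm coordinates.
#'
#' @param image Numeric matrix, rows = y (top to bottom), columns = x.
#' @param region Rectangle `c(xmin, xmax, ymin, ymax)` spanned by the image
#'   nodes.
#' @param level Contour level(s); levels outside the image range yield no
#'   polylines.
#' @return A list with one element per requested level (in order); each
#'   element is a list of polylines, each a matrix with columns `x`, `y`.
#'   Levels without a contour get an empty list.
#' @export
extract_contour <- function(image, region, level) {
  region <- as_region(region)
  if (!is.matrix(image)) stop("image must be a matrix")
  xs <- seq(region[1], region[2], length.out = ncol(image))
  ys <- seq(region[3], region[4], length.out = nrow(image))
  rng <- range(image)
  keep <- level >= rng[1] & level <= rng[2]
  adj <- .interior_levels(level[keep], image)
  out <- rep(list(list()), length(level))
  if (any(keep)) {
    # contourLines wants z[i, j] = value at (x_i, y_j)
    cl <- grDevices::contourLines(xs, ys, t(image), levels = unique(adj))
    got <- split(cl, vapply(cl, `[[`, numeric(1), "level"))
    for (k in which(keep)) {
      lk <- adj[match(k, which(keep))]
      polys <- got[[as.character(lk)]]
      if (!is.null(polys))
        out[[k]] <- lapply(polys, function(p) cbind(x = p$x, y = p$y))
    }
  }
  out
}
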