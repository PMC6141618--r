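#' Build the contour-intersection tracking map
#'
#' Divides each difference-channel image of a [scan_image_pair()] into
#' `n_levels` evenly spaced contours, intersects every horizontal-channel
#' contour with every vertical-channel contour, and stores the intersection
#' coordinates as an ordered 1D array of packed 32-bit entries. The array is
#' row-major over (h level index, v level index) -- the h level is the slow
#' axis, reading "top left to bottom right" -- and level pairs without an
#' intersection hold the reserved [PLACEHOLDER] word so the ordering is
#' preserved. A 200-level map therefore always has 40,000 entries.
#'
#' @param pair A [scan_image_pair()].
#' @param n_levels Contours per channel (default 200).
#' @return A `contour_map`: list with `entries` (numeric vector of packed
#'   words, length `n_levels^2`), `h_levels`, `v_levels`
#'   ([compute_levels()] objects), `region`, and `build_metadata`
#'   (placeholder count/fraction, mean nearest-neighbor intersection
#'   spacing, scan pitch).
#' @seealso [signal_to_index()], [lookup_position()], [track_stream()]
#' @export
build_map <- function(pair, n_levels = 200) {
  stopifnot(inherits(pair, "scan_image_pair"))
  h_levels <- compute_levels(pair$h_image, n_levels)
  v_levels <- compute_levels(pair$v_image, n_levels)
  h_contours <- extract_contour(pair$h_image, pair$region, h_levels$levels)
  v_contours <- extract_contour(pair$v_image, pair$region, v_levels$levels)
  inter <- find_intersections(h_contours, v_contours, pair$region)
  # row-major over (h index slow, v index fast)
  x <- as.vector(t(inter$x))
  y <- as.vector(t(inter$y))
  miss <- is.na(x)
  entries <- rep(PLACEHOLDER, length(x))
  if (any(!miss))
    entries[!miss] <- pack_entry(cbind(x[!miss], y[!miss]), pair$region)
  pts <- cbind(x[!miss], y[!miss])
  meta <- list(
    n_levels = as.integer(n_levels),
    scan_pixel_pitch = pair$pixel_pitch,
    n_entries = length(entries),
    placeholder_count = sum(miss),
    placeholder_fraction = mean(miss),
    mean_nn_spacing = if (nrow(pts) >= 2) mean_nn_distance(pts) else NA_real_)
  structure(list(entries = entries, h_levels = h_levels, v_levels = v_levels,
                 region = pair$region, build_metadata = meta,
                 cache = new.env(parent = emptyenv())),
            class = "contour_map")
}

#' @export
print.contour_map <- function(x, ...) {
  m <- x$build_metadata
  cat(sprintf("Contour-intersection map: %d x %d levels, %d entries\n",
              x$h_levels$n_levels, x$v_levels$n_levels, length(x$entries)))
  cat(sprintf("  region: [%g, %g] x [%g, %g] nm\n", x$region[1], x$region[2],
              x$region[3], x$region[4]))
  cat(sprintf("  placeholders: %d (%.2f%%), mean NN spacing: %.3f nm\n",
              m$placeholder_count, 100 * m$placeholder_fraction,
              m$mean_nn_spacing))
  invisible(x)
}

#' Mean nearest-neighbor distance of a point set
#'
#' Exact nearest-neighbor distances via uniform cell binning (each point is
#' compared against points in its 3x3 cell neighborhood, expanding the
#' search ring when a neighborhood is empty).
#'
#' @param pts Two-column matrix of positions.
#' @return Mean distance from each point to its nearest neighbor.
#' @export
mean_nn_distance <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2) stop("need at least two points")
  ext <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-12)
  cell <- max(ext / max(1, floor(sqrt(n))), 1e-12)
  cx <- as.integer(floor((pts[, 1] - min(pts[, 1])) / cell))
  cy <- as.integer(floor((pts[, 2] - min(pts[, 2])) / cell))
  ncx <- max(cx) + 1L
  ncy <- max(cy) + 1L
  key <- cx + cy * ncx
  cells <- vector("list", ncx * ncy)
  sp <- split(seq_len(n), key)
  cells[as.integer(names(sp)) + 1L] <- sp
  nn <- rep(Inf, n)
  for (cell_pts in sp) {
    kx <- cx[cell_pts[1]]; ky <- cy[cell_pts[1]]
    ring <- 2L
    repeat {
      xs <- max(0L, kx - ring):min(ncx - 1L, kx + ring)
      ys <- max(0L, ky - ring):min(ncy - 1L, ky + ring)
      cand <- unlist(cells[outer(xs, ys * ncx, "+") + 1L], use.names = FALSE)
      if (length(cand) > length(cell_pts)) {
        d2 <- outer(pts[cell_pts, 1], pts[cand, 1], "-")^2 +
              outer(pts[cell_pts, 2], pts[cand, 2], "-")^2
        d2[cbind(seq_along(cell_pts), match(cell_pts, cand))] <- Inf
        best <- apply(d2, 1, min)
        # cells within Chebyshev ring r are guaranteed to contain every
        # point closer than (r - 1) * cell; expand until that holds
        if (max(best) <= ((ring - 1L) * cell)^2 || ring > 64L) {
          nn[cell_pts] <- sqrt(best)
          break
        }
      } else if (ring > 64L) break
      ring <- ring + 1L
    }
  }
  # points whose ring search hit the cap (isolated outliers): brute force
  far <- which(!is.finite(nn))
  for (i in far) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    d2[i] <- Inf
    nn[i] <- sqrt(min(d2))
  }
  mean(nn)
}
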