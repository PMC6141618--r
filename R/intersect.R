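# Contour-intersection geometry: every horizontal-channel contour is checked
# against every vertical-channel contour by exact segment-segment
# intersection on the sub-pixel polylines, with bounding-box culling to keep
# the pair sweep fast.

# Flatten one level's polylines into a segment table.
.segment_table <- function(polys) {
  if (length(polys) == 0L)
    return(list(n = 0L))
  x1 <- y1 <- x2 <- y2 <- numeric(0)
  for (p in polys) {
    np <- nrow(p)
    if (np < 2L) next
    x1 <- c(x1, p[-np, 1]); y1 <- c(y1, p[-np, 2])
    x2 <- c(x2, p[-1L, 1]); y2 <- c(y2, p[-1L, 2])
  }
  if (!length(x1)) return(list(n = 0L))
  list(n = length(x1), x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       xmin = pmin(x1, x2), xmax = pmax(x1, x2),
       ymin = pmin(y1, y2), ymax = pmax(y1, y2),
       bbox = c(min(x1, x2), max(x1, x2), min(y1, y2), max(y1, y2)))
}

# All intersection points between two segment tables (exact 2x2 solves on
# bbox-culled candidate pairs). Returns a two-column matrix (possibly empty).
.cross_segments <- function(a, b) {
  none <- matrix(numeric(0), ncol = 2)
  if (a$n == 0L || b$n == 0L) return(none)
  ai <- which(a$xmax >= b$bbox[1] & a$xmin <= b$bbox[2] &
              a$ymax >= b$bbox[3] & a$ymin <= b$bbox[4])
  if (!length(ai)) return(none)
  abb <- c(min(a$xmin[ai]), max(a$xmax[ai]), min(a$ymin[ai]), max(a$ymax[ai]))
  bi <- which(b$xmax >= abb[1] & b$xmin <= abb[2] &
              b$ymax >= abb[3] & b$ymin <= abb[4])
  if (!length(bi)) return(none)
  ia <- rep(ai, times = length(bi))
  ib <- rep(bi, each = length(ai))
  px <- a$x1[ia]; py <- a$y1[ia]
  rx <- a$x2[ia] - px; ry <- a$y2[ia] - py
  qx <- b$x1[ib]; qy <- b$y1[ib]
  sx <- b$x2[ib] - qx; sy <- b$y2[ib] - qy
  denom <- rx * sy - ry * sx
  ok <- abs(denom) > 0
  t <- u <- rep(NA_real_, length(denom))
  t[ok] <- ((qx - px) * sy - (qy - py) * sx)[ok] / denom[ok]
  u[ok] <- ((qx - px) * ry - (qy - py) * rx)[ok] / denom[ok]
  hit <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
  if (!any(hit)) return(none)
  cbind(px[hit] + t[hit] * rx[hit], py[hit] + t[hit] * ry[hit])
}

#' Intersect horizontal- and vertical-channel contours
#'
#' For every pair of contour levels, finds where the horizontal-channel
#' polyline crosses the vertical-channel polyline by segment-segment
#' intersection. If a level pair crosses more than once, the intersection
#' nearest the region center is kept (the central branch is the physical
#' one for apex-centered maps); pairs that never cross map to none.
#'
#' @param h_contours,v_contours Per-level polyline lists as returned by
#'   [extract_contour()], in the same coordinate frame.
#' @param region Map rectangle in nm (used for the center tie-break).
#' @return A list with matrices `x` and `y` of dimension
#'   `length(h_contours) x length(v_contours)`; absent intersections are
#'   `NA` (absence is encoded, not raised).
#' @export
find_intersections <- function(h_contours, v_contours, region) {
  region <- as_region(region)
  cx <- mean(region[1:2]); cy <- mean(region[3:4])
  hseg <- lapply(h_contours, .segment_table)
  vseg <- lapply(v_contours, .segment_table)
  nh <- length(hseg); nv <- length(vseg)
  X <- Y <- matrix(NA_real_, nh, nv)
  for (i in seq_len(nh)) {
    a <- hseg[[i]]
    if (a$n == 0L) next
    for (j in seq_len(nv)) {
      pts <- .cross_segments(a, vseg[[j]])
      if (!nrow(pts)) next
      if (nrow(pts) > 1L) {
        d2 <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2
        pts <- pts[which.min(d2), , drop = FALSE]
      }
      X[i, j] <- pts[1, 1]
      Y[i, j] <- pts[1, 2]
    }
  }
  list(x = X, y = Y)
}
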