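# Single-molecule demonstration: 2D Gaussian localization of sparse
# emitters in raster-scan images and centroid-based drift measurement.

.image_pixel <- function(image) {
  p <- attr(image, "pixel")
  if (is.null(p)) 1 else p
}

# Separable Gaussian smoothing (sigma in px) with edge renormalization.
.smooth_image <- function(image, sigma = 1) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  sm_dim <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    w <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      rows_to <- max(1, 1 - sh):min(nrow(m), nrow(m) - sh)
      rows_from <- rows_to + sh
      out[rows_to, ] <- out[rows_to, ] + k[i] * m[rows_from, ]
      w[rows_to, ] <- w[rows_to, ] + k[i]
    }
    out / w
  }
  t(sm_dim(t(sm_dim(image))))
}

#' Detect candidate spots in a sparse-emitter image
#'
#' Smooths the image and finds local maxima exceeding
#' `background + threshold_sigmas * noise`, where background and noise are
#' the image median and MAD. Sparse, well-separated fields make this simple
#' thresholding sufficient.
#'
#' @param image A `raster_image` or plain matrix of counts.
#' @param threshold_sigmas Detection threshold in noise sigmas (default 5).
#' @param smooth_sigma Smoothing sigma in px (default 1).
#' @param min_distance Minimum spot separation in px (default 4).
#' @return Data.frame with columns `row`, `col` (pixel indices) and
#'   `value` (smoothed peak height), ordered by decreasing value.
#' @export
detect_spots <- function(image, threshold_sigmas = 5, smooth_sigma = 1,
                         min_distance = 4) {
  im <- .smooth_image(unclass(image), smooth_sigma)
  bg <- stats::median(im)
  noise <- stats::mad(im)
  thr <- bg + threshold_sigmas * max(noise, 1e-12)
  nr <- nrow(im); nc <- ncol(im)
  # strict local maxima over the 8-neighborhood
  is_max <- im > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rt <- max(1, 1 + dr):min(nr, nr + dr)
    ct <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rt, ct] <- im[rt - dr, ct - dc]
    is_max <- is_max & (im >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  v <- im[idx]
  ord <- order(v, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; v <- v[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1L):nrow(idx)
      d <- sqrt((idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2)
      keep[j][d < min_distance] <- FALSE
    }
  }
  data.frame(row = idx[keep, 1], col = idx[keep, 2], value = v[keep])
}

#' Fit a 2D Gaussian to a single spot
#'
#' Nonlinear least squares of
#' `amplitude * exp(-((x - x0)^2 / 2 sx^2 + (y - y0)^2 / 2 sy^2)) + offset`
#' (elliptical: the two widths are fitted independently), initialized from
#' the centroid of mass and second moments. Centroid standard errors come
#' from the fit covariance. On non-convergence the moments-based estimate is
#' returned with `converged = FALSE`.
#'
#' @param image A `raster_image` or matrix of counts.
#' @param window Optional integer vector `c(row_min, row_max, col_min,
#'   col_max)` restricting the fit to a sub-image containing one dominant
#'   spot; at least 5x5 pixels.
#' @return A `gaussian_fit_2d`: list with `centroid` (nm, image-frame),
#'   `centroid_px` (pixel units, col/row), `sigma` (nm), `amplitude`,
#'   `offset`, `centroid_se` (nm), `converged`.
#' @export
fit_gaussian_2d <- function(image, window = NULL) {
  pixel <- .image_pixel(image)
  region <- attr(image, "region")
  im <- unclass(image)
  if (is.null(window)) window <- c(1L, nrow(im), 1L, ncol(im))
  if (window[2] - window[1] < 4L || window[4] - window[3] < 4L)
    stop("fit window must be at least 5x5 pixels")
  sub <- im[window[1]:window[2], window[3]:window[4], drop = FALSE]
  rows <- window[1]:window[2]; cols <- window[3]:window[4]
  d <- data.frame(r = rep(rows, times = length(cols)),
                  c = rep(cols, each = length(rows)),
                  z = as.vector(sub))
  off0 <- stats::median(d$z)
  w <- pmax(d$z - off0, 0)
  if (sum(w) <= 0) w <- rep(1, nrow(d))
  r0 <- sum(w * d$r) / sum(w); c0 <- sum(w * d$c) / sum(w)
  sr0 <- sqrt(max(sum(w * (d$r - r0)^2) / sum(w), 0.25))
  sc0 <- sqrt(max(sum(w * (d$c - c0)^2) / sum(w), 0.25))
  amp0 <- max(d$z) - off0
  to_nm <- function(col_px, row_px) {
    if (is.null(region)) c(col_px * pixel, row_px * pixel)
    else c(region[1] + (col_px - 0.5) * pixel, region[3] + (row_px - 0.5) * pixel)
  }
  moments_fit <- function() {
    cen <- to_nm(c0, r0)
    structure(list(centroid = cen, centroid_px = c(x = c0, y = r0),
                   sigma = c(x = sc0 * pixel, y = sr0 * pixel),
                   amplitude = amp0, offset = off0,
                   centroid_se = c(x = NA_real_, y = NA_real_),
                   converged = FALSE),
              class = "gaussian_fit_2d")
  }
  if (amp0 <= 0) return(moments_fit())
  do_fit <- function(w, start) tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((c - x0)^2 / (2 * sx^2) + (r - y0)^2 / (2 * sy^2))) + off,
      data = d, weights = w, start = start,
      lower = c(0, min(cols) - 1, min(rows) - 1, 0.2, 0.2, -Inf),
      upper = c(Inf, max(cols) + 1, max(rows) + 1, diff(range(cols)) + 1,
                diff(range(rows)) + 1, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  start0 <- list(A = amp0, x0 = c0, y0 = r0, sx = sc0, sy = sr0, off = off0)
  # two-pass counting-noise weights: a first fit locates the spot, then the
  # refit weights each pixel by the model-predicted variance (Poisson:
  # var = mean), which makes the fit covariance an honest error estimate
  fit <- do_fit(1 / pmax(d$z, 1), start0)
  if (!is.null(fit) && fit$convInfo$isConv) {
    cf1 <- as.list(stats::coef(fit))
    mu <- cf1$A * exp(-((d$c - cf1$x0)^2 / (2 * cf1$sx^2) +
                        (d$r - cf1$y0)^2 / (2 * cf1$sy^2))) + cf1$off
    refit <- do_fit(1 / pmax(mu, 1e-2), cf1)
    if (!is.null(refit) && refit$convInfo$isConv) fit <- refit
  }
  if (is.null(fit) || !fit$convInfo$isConv) return(moments_fit())
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  # a fit that collapsed onto the flat background is not a detection
  if (!is.finite(se[["x0"]]) || !is.finite(se[["y0"]])) return(moments_fit())
  cen <- to_nm(cf[["x0"]], cf[["y0"]])
  structure(list(centroid = cen,
                 centroid_px = c(x = cf[["x0"]], y = cf[["y0"]]),
                 sigma = c(x = abs(cf[["sx"]]) * pixel,
                           y = abs(cf[["sy"]]) * pixel),
                 amplitude = cf[["A"]], offset = cf[["off"]],
                 centroid_se = c(x = se[["x0"]] * pixel,
                                 y = se[["y0"]] * pixel),
                 converged = TRUE),
            class = "gaussian_fit_2d")
}

# Fit every detected spot in an image; returns a data.frame of centroids in
# pixel units (x = col, y = row) with fit metadata.
.fit_all_spots <- function(image, window_halfwidth = 6, ...) {
  spots <- detect_spots(image, ...)
  out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                    se_x_px = numeric(0), se_y_px = numeric(0),
                    converged = logical(0))
  pixel <- .image_pixel(image)
  for (i in seq_len(nrow(spots))) {
    win <- c(max(1L, spots$row[i] - window_halfwidth),
             min(nrow(image), spots$row[i] + window_halfwidth),
             max(1L, spots$col[i] - window_halfwidth),
             min(ncol(image), spots$col[i] + window_halfwidth))
    f <- fit_gaussian_2d(image, win)
    out[nrow(out) + 1L, ] <- list(f$centroid_px[["x"]], f$centroid_px[["y"]],
                                  f$centroid_se[["x"]] / pixel,
                                  f$centroid_se[["y"]] / pixel, f$converged)
  }
  out
}

#' Localize the fiducial apex from backscatter and luminescence images
#'
#' The apex position is the 2D Gaussian centroid of the luminescence image.
#' As a cross-check, the backscatter image's brightest feature is located by
#' smoothing and intensity-weighted centroiding; the two detection schemes
#' agree when the backscatter apex lies within one fitted sigma of the
#' luminescence centroid.
#'
#' @param backscatter_image,luminescence_image Co-registered `raster_image`s
#'   covering the apex.
#' @return List with `position` (nm, the luminescence centroid),
#'   `backscatter_position` (nm), `agreement` (logical), `fit`
#'   (the luminescence `gaussian_fit_2d`).
#' @export
localize_apex <- function(backscatter_image, luminescence_image) {
  lum_spots <- detect_spots(luminescence_image)
  if (nrow(lum_spots) == 0L) stop("no spot found in the luminescence image")
  pixel <- .image_pixel(luminescence_image)
  region <- attr(luminescence_image, "region")
  win_hw <- 8L
  win <- c(max(1L, lum_spots$row[1] - win_hw),
           min(nrow(luminescence_image), lum_spots$row[1] + win_hw),
           max(1L, lum_spots$col[1] - win_hw),
           min(ncol(luminescence_image), lum_spots$col[1] + win_hw))
  fit <- fit_gaussian_2d(luminescence_image, win)
  # backscatter apex: smoothed intensity-weighted centroid above half max;
  # noise estimated from the lower half so a broad spot cannot inflate it
  bim <- .smooth_image(unclass(backscatter_image), 1.5)
  lower <- bim[bim <= stats::median(bim)]
  noise <- max(stats::mad(lower, center = stats::median(bim)), 1e-12)
  if (max(bim) <= stats::median(bim) + 5 * noise)
    stop("no spot found in the backscatter image")
  thr <- stats::median(bim) + 0.5 * (max(bim) - stats::median(bim))
  sel <- which(bim >= thr, arr.ind = TRUE)
  wgt <- bim[sel] - thr
  r0 <- sum(wgt * sel[, 1]) / sum(wgt)
  c0 <- sum(wgt * sel[, 2]) / sum(wgt)
  bpixel <- .image_pixel(backscatter_image)
  bregion <- attr(backscatter_image, "region")
  bpos <- if (is.null(bregion)) c(c0 * bpixel, r0 * bpixel) else
    c(bregion[1] + (c0 - 0.5) * bpixel, bregion[3] + (r0 - 0.5) * bpixel)
  dist <- sqrt(sum((bpos - fit$centroid)^2))
  agreement <- dist <= mean(fit$sigma)
  list(position = fit$centroid, backscatter_position = bpos,
       agreement = agreement, fit = fit)
}

#' Measure drift as the mean centroid displacement between two scans
#'
#' Detects and Gaussian-fits every emitter in two images of the same region
#' taken before and after a drift interval, matches centroids by nearest
#' neighbor within `matching_radius`, and reports per-emitter and mean
#' displacement in pixels (after - before).
#'
#' @param image_before,image_after `raster_image`s of the same region.
#' @param matching_radius Maximum matching distance in px (default 10).
#' @return A `drift_measurement`: list with `per_emitter` (data.frame of
#'   matched before/after centroids and displacements in px),
#'   `mean_displacement` (named `c(x, y)` in px), `pixel_size` (nm),
#'   `n_matched`, `n_unmatched`.
#' @export
measure_drift <- function(image_before, image_after, matching_radius = 10) {
  fb <- .fit_all_spots(image_before)
  fa <- .fit_all_spots(image_after)
  if (nrow(fb) == 0L || nrow(fa) == 0L)
    stop("no emitters detected in one of the images")
  # mutual nearest neighbors within the radius: a pair is accepted only if
  # each centroid is the other's nearest, which rejects emitters whose true
  # partner drifted out of the field
  D <- outer(fb$x_px, fa$x_px, "-")^2 + outer(fb$y_px, fa$y_px, "-")^2
  nearest_a <- apply(D, 1, which.min)
  nearest_b <- apply(D, 2, which.min)
  rows <- list()
  for (i in seq_len(nrow(fb))) {
    j <- nearest_a[i]
    if (nearest_b[j] == i && sqrt(D[i, j]) <= matching_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        x_before = fb$x_px[i], y_before = fb$y_px[i],
        x_after = fa$x_px[j], y_after = fa$y_px[j],
        dx_px = fa$x_px[j] - fb$x_px[i], dy_px = fa$y_px[j] - fb$y_px[i])
  }
  if (!length(rows)) stop("no emitter matches within the matching radius")
  per <- do.call(rbind, rows)
  structure(list(per_emitter = per,
                 mean_displacement = c(x = mean(per$dx_px),
                                       y = mean(per$dy_px)),
                 pixel_size = .image_pixel(image_before),
                 n_matched = nrow(per),
                 n_unmatched = (nrow(fb) - nrow(per)) +
                   (nrow(fa) - nrow(per))),
            class = "drift_measurement")
}

#' @export
print.drift_measurement <- function(x, ...) {
  cat(sprintf("Drift measurement: %d matched emitters (%d unmatched)\n",
              x$n_matched, x$n_unmatched))
  cat(sprintf("  mean displacement: %.3f px (X), %.3f px (Y)  [pixel = %g nm]\n",
              x$mean_displacement["x"], x$mean_displacement["y"],
              x$pixel_size))
  invisible(x)
}
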