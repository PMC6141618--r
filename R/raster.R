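#' Field of point emitters
#'
#' A sparse collection of diffraction-limited fluorescent emitters for the
#' confocal raster-scan simulator. Generated test fields keep a configurable
#' minimum separation so individual molecules remain optically resolvable.
#'
#' @param positions Two-column matrix or data.frame of emitter positions (nm).
#' @param brightness Counts/s per emitter (recycled).
#' @param psf_sigma Gaussian point-spread-function sigma in nm (default 100).
#' @param background Background rate in counts/s (default 50).
#' @return An object of class `emitter_field`.
#' @export
emitter_field <- function(positions, brightness = 1e5, psf_sigma = 100,
                          background = 50) {
  positions <- as.matrix(as.data.frame(positions))
  if (ncol(positions) != 2L || any(!is.finite(positions)))
    stop("positions must be a two-column numeric matrix")
  colnames(positions) <- c("x", "y")
  stop_if_not_scalar_pos(psf_sigma, "psf_sigma")
  if (background < 0) stop("background must be >= 0")
  brightness <- rep_len(as.numeric(brightness), nrow(positions))
  if (any(brightness <= 0)) stop("brightness must be positive")
  structure(list(positions = positions, brightness = brightness,
                 psf_sigma = psf_sigma, background = background),
            class = "emitter_field")
}

#' Randomly placed, well-separated emitter field
#'
#' @param n Number of emitters.
#' @param region Placement rectangle in nm.
#' @param min_separation Minimum pairwise distance in nm (default
#'   `5 * psf_sigma`, comfortably resolvable).
#' @param seed Optional integer seed.
#' @inheritParams emitter_field
#' @return An `emitter_field`.
#' @export
random_emitter_field <- function(n, region = c(-900, 900, -900, 900),
                                 psf_sigma = 100,
                                 min_separation = 5 * psf_sigma,
                                 brightness = 1e5, background = 50,
                                 seed = NULL) {
  region <- as_region(region)
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pts) < n && tries < 10000L) {
      p <- c(stats::runif(1, region[1], region[2]),
             stats::runif(1, region[3], region[4]))
      if (nrow(pts) == 0L ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_separation)
        pts <- rbind(pts, p)
      tries <- tries + 1L
    }
    if (nrow(pts) < n) stop("could not place emitters with the requested separation")
    emitter_field(pts, brightness = brightness, psf_sigma = psf_sigma,
                  background = background)
  })
}

#' Render a confocal raster-scan image
#'
#' Scans a rectangular region left-to-right, top-to-bottom and accumulates
#' counts per pixel for dwell time `dwell`. For an [emitter_field()], each
#' emitter contributes a 2D Gaussian spot of width `psf_sigma` whose total
#' (integrated over the full image) equals `brightness * dwell`; optional
#' shot noise draws each pixel from a Poisson law. For a
#' [qapd_response_model()], the total (sum) backscatter channel is rendered,
#' scaled by `count_rate` counts/s at the peak.
#'
#' @param obj An `emitter_field` or `qapd_response_model`.
#' @param region Imaged rectangle `c(xmin, xmax, ymin, ymax)` in nm.
#' @param pixel Pixel size in nm (default 60). The region extent must be an
#'   integer number of pixels per axis; pixels are sampled at their centers.
#' @param dwell Per-pixel dwell time in s (default 1e-3).
#' @param shot_noise Add Poisson shot noise? (default TRUE)
#' @param seed Optional integer seed for the shot noise.
#' @param ... Passed to methods.
#' @return A `raster_image`: a numeric matrix of counts (rows = y top to
#'   bottom, columns = x left to right) with attributes `region`, `pixel`,
#'   `dwell`.
#' @export
render_raster <- function(obj, region, pixel = 60, dwell = 1e-3,
                          shot_noise = TRUE, seed = NULL, ...) {
  UseMethod("render_raster")
}

.raster_grid <- function(region, pixel) {
  region <- as_region(region)
  stop_if_not_scalar_pos(pixel, "pixel")
  nx <- round((region[2] - region[1]) / pixel)
  ny <- round((region[4] - region[3]) / pixel)
  if (nx < 1 || ny < 1 ||
      abs(nx * pixel - (region[2] - region[1])) > 1e-9 ||
      abs(ny * pixel - (region[4] - region[3])) > 1e-9)
    stop("region extent must be an integer number of pixels per axis")
  list(region = region, nx = nx, ny = ny,
       xc = region[1] + (seq_len(nx) - 0.5) * pixel,
       yc = region[3] + (seq_len(ny) - 0.5) * pixel)
}

.finish_raster <- function(counts, g, pixel, dwell, shot_noise, seed) {
  if (shot_noise)
    counts <- with_seed(seed, matrix(stats::rpois(length(counts), counts),
                                     nrow = nrow(counts)))
  structure(counts, region = g$region, pixel = pixel, dwell = dwell,
            class = c("raster_image", "matrix", "array"))
}

#' @rdname render_raster
#' @export
render_raster.emitter_field <- function(obj, region, pixel = 60, dwell = 1e-3,
                                        shot_noise = TRUE, seed = NULL, ...) {
  stop_if_not_scalar_pos(dwell, "dwell")
  g <- .raster_grid(region, pixel)
  counts <- matrix(obj$background * dwell, nrow = g$ny, ncol = g$nx)
  s2 <- obj$psf_sigma^2
  norm <- pixel^2 / (2 * pi * s2)
  for (e in seq_len(nrow(obj$positions))) {
    dx2 <- (g$xc - obj$positions[e, 1])^2
    dy2 <- (g$yc - obj$positions[e, 2])^2
    counts <- counts + obj$brightness[e] * dwell * norm *
      exp(-dy2 / (2 * s2)) %o% exp(-dx2 / (2 * s2))
  }
  .finish_raster(counts, g, pixel, dwell, shot_noise, seed)
}

#' @rdname render_raster
#' @param count_rate Peak backscatter count rate in counts/s (default 1e5),
#'   applied to the model's unit-peak sum channel.
#' @export
render_raster.qapd_response_model <- function(obj, region, pixel = 60,
                                              dwell = 1e-3, shot_noise = TRUE,
                                              seed = NULL, count_rate = 1e5,
                                              ...) {
  stop_if_not_scalar_pos(dwell, "dwell")
  g <- .raster_grid(region, pixel)
  gx <- matrix(rep(g$xc, each = g$ny), nrow = g$ny)
  gy <- matrix(rep(g$yc, times = g$nx), nrow = g$ny)
  counts <- obj$sum_field(gx, gy) / obj$sum_peak * count_rate * dwell
  .finish_raster(counts, g, pixel, dwell, shot_noise, seed)
}

#' Simulated backscatter and luminescence images of the fiducial tip
#'
#' Renders the pair of co-registered images used to localize the tip apex:
#' the broad backscatter (sum-channel) spot and the luminescence emission
#' spot, sharing the same center but carrying independent shot noise.
#'
#' @param center Apex position in nm.
#' @param region Imaged rectangle in nm (default 1.8 um x 1.8 um).
#' @param pixel Pixel size in nm (default 60).
#' @param psf_sigma Luminescence spot sigma in nm (default 150).
#' @param backscatter_sigma Backscatter spot sigma in nm (default 250).
#' @param brightness Luminescence emitter rate in counts/s.
#' @param dwell Per-pixel dwell in s.
#' @param shot_noise Add Poisson noise to both images?
#' @param seed Optional integer seed.
#' @return List with `backscatter` and `luminescence` raster images.
#' @export
simulate_tip_images <- function(center = c(0, 0), region = c(-900, 900, -900, 900),
                                pixel = 60, psf_sigma = 150,
                                backscatter_sigma = 250, brightness = 2e6,
                                dwell = 1e-3, shot_noise = TRUE, seed = NULL) {
  lum_field <- emitter_field(matrix(center, ncol = 2), brightness = brightness,
                             psf_sigma = psf_sigma, background = 20)
  back_field <- emitter_field(matrix(center, ncol = 2),
                              brightness = brightness * 10,
                              psf_sigma = backscatter_sigma, background = 100)
  with_seed(seed, list(
    backscatter = render_raster(back_field, region, pixel, dwell,
                                shot_noise = shot_noise, seed = NULL),
    luminescence = render_raster(lum_field, region, pixel, dwell,
                                 shot_noise = shot_noise, seed = NULL)))
}
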