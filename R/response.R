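#' Quadrant-detector response model
#'
#' Constructs the deterministic mapping from fiducial position to the
#' normalized difference signals of a quadrant avalanche photodiode (QAPD).
#' The two difference channels (left-right and bottom-top) are divided by the
#' total signal, so the model returns dimensionless ratios in \[-1, 1\] that
#' vary smoothly and, within the monotone region, strictly monotonically with
#' the respective axis.
#'
#' The default functional form is
#' \deqn{h(x, y) = \tanh((x + \kappa y)/w_x)\, g(r), \quad
#'       v(x, y) = \tanh((y + \kappa x)/w_y)\, g(r),}
#' with \eqn{g(r) = \exp(-r^2 / 2\sigma_g^2)} a broad Gaussian envelope and
#' \eqn{\kappa} a small shear coupling the two channels. The shear and
#' envelope bend the iso-signal contours into the curved, tilted grids seen
#' on a real detector while preserving point antisymmetry
#' (\eqn{h(-x,-y) = -h(x,y)}) and strict monotonicity of \eqn{h} in \eqn{x}
#' (and \eqn{v} in \eqn{y}) over the monotone region. The total (sum) signal
#' is a broad positive Gaussian of the backscattering spot.
#'
#' Coordinates follow the image convention: x increases rightward, y
#' increases downward, origin at the scan-region center (the fiducial apex).
#'
#' @param w Tanh length scale in nm, length 1 or 2 (x, y). Default 100 nm,
#'   which keeps the response monotone over more than +/-100 nm.
#' @param envelope_sigma Gaussian envelope scale in nm (default 300).
#' @param kappa Dimensionless shear coupling between channels (default 0.1).
#' @param sum_sigma Length scale of the total-signal spot in nm (default 500).
#' @param sum_peak Peak total signal, arbitrary units (default 1).
#' @param monotone_halfwidth Half-width in nm of the square region over which
#'   monotonicity is guaranteed (default 100).
#' @param domain_halfwidth Half-width in nm of the model's defined domain
#'   (default 1000). Evaluations outside raise an error.
#' @return An object of class `qapd_response_model` with fields `h_field`,
#'   `v_field`, `sum_field` (vectorized functions of x, y in nm),
#'   `monotone_region` and `domain` rectangles.
#' @seealso [evaluate_response()], [scan_image_pair()], [sample_stream()]
#' @export
#' @examples
#' m <- qapd_response_model()
#' evaluate_response(m, c(0, 0))      # apex center: both channels zero
#' evaluate_response(m, c(25, -10))
qapd_response_model <- function(w = 100, envelope_sigma = 300, kappa = 0.1,
                                sum_sigma = 500, sum_peak = 1,
                                monotone_halfwidth = 100,
                                domain_halfwidth = 1000) {
  w <- per_axis(w, "w")
  stop_if_not_scalar_pos(envelope_sigma, "envelope_sigma")
  stop_if_not_scalar_pos(sum_sigma, "sum_sigma")
  stop_if_not_scalar_pos(sum_peak, "sum_peak")
  stop_if_not_scalar_pos(monotone_halfwidth, "monotone_halfwidth")
  stop_if_not_scalar_pos(domain_halfwidth, "domain_halfwidth")
  if (!is.numeric(kappa) || length(kappa) != 1L || abs(kappa) >= 1)
    stop("kappa must be a scalar with |kappa| < 1")
  force(envelope_sigma); force(sum_sigma); force(sum_peak)
  env <- function(x, y) exp(-(x^2 + y^2) / (2 * envelope_sigma^2))
  model <- list(
    h_field = function(x, y) tanh((x + kappa * y) / w[1]) * env(x, y),
    v_field = function(x, y) tanh((y + kappa * x) / w[2]) * env(x, y),
    sum_field = function(x, y) sum_peak * exp(-(x^2 + y^2) / (2 * sum_sigma^2)),
    w = w, envelope_sigma = envelope_sigma, kappa = kappa,
    sum_sigma = sum_sigma, sum_peak = sum_peak,
    monotone_region = c(-1, 1, -1, 1) * monotone_halfwidth,
    domain = c(-1, 1, -1, 1) * domain_halfwidth)
  class(model) <- "qapd_response_model"
  model
}

#' @export
print.qapd_response_model <- function(x, ...) {
  cat("QAPD response model\n")
  cat(sprintf("  tanh scale w: (%g, %g) nm, envelope sigma: %g nm, shear kappa: %g\n",
              x$w[1], x$w[2], x$envelope_sigma, x$kappa))
  cat(sprintf("  monotone region: +/-%g nm, domain: +/-%g nm\n",
              x$monotone_region[2], x$domain[2]))
  invisible(x)
}

#' Evaluate the noiseless detector response at a position
#'
#' @param model A [qapd_response_model()].
#' @param pos Position in nm: a length-2 vector `c(x, y)` or a two-column
#'   matrix/data.frame of positions.
#' @return A data.frame with columns `h_norm`, `v_norm`, `total` (one row per
#'   position). Repeated calls are identical; no noise is added.
#' @export
evaluate_response <- function(model, pos) {
  stopifnot(inherits(model, "qapd_response_model"))
  if (is.data.frame(pos)) pos <- as.matrix(pos[, c("x", "y")])
  if (is.null(dim(pos))) pos <- matrix(as.numeric(pos), ncol = 2L)
  x <- pos[, 1]; y <- pos[, 2]
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("positions must be finite")
  if (!all(in_region(x, y, model$domain)))
    stop("position outside the response model domain")
  data.frame(h_norm = model$h_field(x, y), v_norm = model$v_field(x, y),
             total = model$sum_field(x, y))
}

#' Simulated scan of the detector response over a region
#'
#' Raster-scans the (noiseless or noisy) response model over a square grid of
#' scan nodes, producing the co-registered horizontal and vertical
#' difference-channel images from which a tracking map is built. Nodes are
#' spaced `pixel_pitch` apart; the region spans the node centers, so a
#' 100 nm x 100 nm region at 0.5 nm pitch is a 201 x 201 image.
#'
#' @param model A [qapd_response_model()].
#' @param region Scan rectangle `c(xmin, xmax, ymin, ymax)` in nm
#'   (default 100 nm x 100 nm centered on the apex).
#' @param pixel_pitch Node spacing in nm (default 0.5).
#' @param noise_rms RMS noise added to each normalized sample (default 0: the
#'   slow map-building scan is treated as averaged to negligible noise).
#' @param seed Optional integer seed for the scan noise.
#' @return A `scan_image_pair`: list with matrices `h_image`, `v_image`
#'   (rows = y scanned top to bottom, columns = x left to right), `region`,
#'   `pixel_pitch`, and node coordinate vectors `xs`, `ys`.
#' @export
scan_image_pair <- function(model, region = c(-50, 50, -50, 50),
                            pixel_pitch = 0.5, noise_rms = 0, seed = NULL) {
  stopifnot(inherits(model, "qapd_response_model"))
  region <- as_region(region)
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  nx <- round((region[2] - region[1]) / pixel_pitch) + 1L
  ny <- round((region[4] - region[3]) / pixel_pitch) + 1L
  if (abs((nx - 1L) * pixel_pitch - (region[2] - region[1])) > 1e-9 ||
      abs((ny - 1L) * pixel_pitch - (region[4] - region[3])) > 1e-9)
    stop("region extent must be an integer multiple of pixel_pitch")
  xs <- region[1] + (seq_len(nx) - 1L) * pixel_pitch
  ys <- region[3] + (seq_len(ny) - 1L) * pixel_pitch
  gx <- matrix(rep(xs, each = ny), nrow = ny)
  gy <- matrix(rep(ys, times = nx), nrow = ny)
  h <- model$h_field(gx, gy)
  v <- model$v_field(gx, gy)
  if (noise_rms > 0) {
    with_seed(seed, {
      h <- h + stats::rnorm(length(h), sd = noise_rms)
      v <- v + stats::rnorm(length(v), sd = noise_rms)
    })
  }
  structure(list(h_image = h, v_image = v, region = region,
                 pixel_pitch = pixel_pitch, xs = xs, ys = ys),
            class = "scan_image_pair")
}
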