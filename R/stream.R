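#' Digitized detector sample stream
#'
#' Samples the detector response along a fiducial trajectory at the
#' digitization rate (1 MHz by default, the rate at which the normalized
#' difference values are produced). Independent zero-mean Gaussian noise of
#' RMS `noise_rms` is added to each normalized ratio after normalization
#' (the small-signal equivalent of quadrant-current noise surviving the
#' difference-over-sum normalization).
#'
#' @param model A [qapd_response_model()].
#' @param trajectory Either a static position `c(x, y)` in nm or a
#'   data.frame with columns `t`, `x`, `y`; positions at sample times are
#'   linearly interpolated.
#' @param duration Stream duration in s (required for a static trajectory;
#'   defaults to the trajectory's time span otherwise).
#' @param digitization_rate Samples per second (default 1e6).
#' @param noise_rms RMS noise on each of `h_norm` and `v_norm` (default 0.01).
#' @param seed Optional integer seed; equal seeds give identical streams.
#' @return A data.frame with columns `t`, `h_norm`, `v_norm`, `total`.
#' @export
sample_stream <- function(model, trajectory, duration = NULL,
                          digitization_rate = 1e6, noise_rms = 0.01,
                          seed = NULL) {
  stopifnot(inherits(model, "qapd_response_model"))
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  stop_if_not_scalar_pos(digitization_rate, "digitization_rate")
  if (is.numeric(trajectory) && is.null(dim(trajectory))) {
    if (is.null(duration)) stop("duration is required for a static trajectory")
    pos_fun <- function(t) cbind(rep(trajectory[1], length(t)),
                                 rep(trajectory[2], length(t)))
  } else {
    trajectory <- as.data.frame(trajectory)
    if (nrow(trajectory) == 0L) stop("empty trajectory")
    if (is.null(duration)) duration <- max(trajectory$t) - min(trajectory$t)
    if (duration <= 0) stop("trajectory must span a positive duration")
    if (max(trajectory$t) - min(trajectory$t) < duration - 1e-12)
      stop("trajectory does not cover the requested duration")
    pos_fun <- function(t) cbind(
      stats::approx(trajectory$t, trajectory$x, xout = t, rule = 2)$y,
      stats::approx(trajectory$t, trajectory$y, xout = t, rule = 2)$y)
  }
  n <- round(duration * digitization_rate)
  if (n < 1) stop("duration too short for the digitization rate")
  t <- (seq_len(n) - 1L) / digitization_rate
  p <- pos_fun(t)
  resp <- evaluate_response(model, p)
  if (noise_rms > 0) {
    with_seed(seed, {
      resp$h_norm <- resp$h_norm + stats::rnorm(n, sd = noise_rms)
      resp$v_norm <- resp$v_norm + stats::rnorm(n, sd = noise_rms)
    })
  }
  cbind(data.frame(t = t), resp)
}
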