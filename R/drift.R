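#' Mechanical drift model
#'
#' Sample drift is modeled as a linear ramp plus a band-limited stochastic
#' fluctuation per axis. The fluctuation is synthesized in the frequency
#' domain with a Lorentzian (Ornstein-Uhlenbeck-like) power spectrum that is
#' truncated at `fluct_cutoff`, so all stochastic power sits below the cutoff
#' -- drift in this instrument class is concentrated below ~20 Hz. The
#' default calibration keeps open-loop 10 s peak-to-peak excursions within
#' the tens-of-nanometer range (<= 55 nm in X, <= 35 nm in Y).
#'
#' @param linear_rate Per-axis ramp in nm/s, length 1 or 2 (default
#'   `c(3, -2)`).
#' @param fluct_amplitude Stationary standard deviation of the fluctuation in
#'   nm per axis (default `c(5, 3)`).
#' @param fluct_corner Lorentzian corner frequency in Hz (default 0.5).
#' @param fluct_cutoff Hard spectral cutoff in Hz (default 20); no stochastic
#'   power is generated above it.
#' @param seed Optional integer seed attached to the model; realizations are
#'   reproducible from it.
#' @return An object of class `drift_model`.
#' @seealso [make_drift()]
#' @export
drift_model <- function(linear_rate = c(3, -2), fluct_amplitude = c(5, 3),
                        fluct_corner = 0.5, fluct_cutoff = 20, seed = NULL) {
  linear_rate <- per_axis(linear_rate, "linear_rate")
  fluct_amplitude <- per_axis(fluct_amplitude, "fluct_amplitude")
  if (any(fluct_amplitude < 0)) stop("fluct_amplitude must be >= 0")
  stop_if_not_scalar_pos(fluct_corner, "fluct_corner")
  stop_if_not_scalar_pos(fluct_cutoff, "fluct_cutoff")
  if (fluct_corner >= fluct_cutoff) stop("fluct_corner must be below fluct_cutoff")
  structure(list(linear_rate = linear_rate, fluct_amplitude = fluct_amplitude,
                 fluct_corner = fluct_corner, fluct_cutoff = fluct_cutoff,
                 seed = seed),
            class = "drift_model")
}

# Band-limited stationary fluctuation of length n at sample rate `rate`,
# synthesized from a truncated Lorentzian amplitude spectrum with random
# Gaussian Fourier coefficients. Returns a real vector with stationary sd
# `amplitude` (in expectation).
.band_limited_noise <- function(n, rate, amplitude, corner, cutoff) {
  if (amplitude == 0) return(numeric(n))
  freqs <- seq_len(n %/% 2) * rate / n          # positive-frequency bins
  shape <- 1 / (1 + (freqs / corner)^2)
  shape[freqs > cutoff] <- 0
  if (!any(shape > 0)) return(numeric(n))
  coef <- complex(real = stats::rnorm(length(freqs)),
                  imaginary = stats::rnorm(length(freqs))) * sqrt(shape / 2)
  spec <- complex(length.out = n)
  spec[2:(length(freqs) + 1L)] <- coef
  spec[n:(n - length(freqs) + 1L)] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  # raw stationary sd is sqrt(2 * sum(shape)) / n; rescale to `amplitude`
  x * amplitude * n / sqrt(2 * sum(shape))
}

#' Generate a drift trajectory
#'
#' @param model A [drift_model()].
#' @param duration Duration in s.
#' @param rate Sample rate in Hz.
#' @param seed Optional seed overriding `model$seed`; `NULL` falls back to
#'   the model seed, and if both are `NULL` the current RNG stream is used.
#' @return A data.frame with columns `t` (s), `x`, `y` (nm), starting at
#'   (0, 0) at t = 0.
#' @export
make_drift <- function(model, duration, rate, seed = NULL) {
  stopifnot(inherits(model, "drift_model"))
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(rate, "rate")
  n <- round(duration * rate) + 1L   # endpoints inclusive: t = 0 .. duration
  if (n < 2) stop("duration too short for the requested rate")
  t <- (seq_len(n) - 1L) / rate
  if (is.null(seed)) seed <- model$seed
  with_seed(seed, {
    fx <- .band_limited_noise(n, rate, model$fluct_amplitude[1],
                              model$fluct_corner, model$fluct_cutoff)
    fy <- .band_limited_noise(n, rate, model$fluct_amplitude[2],
                              model$fluct_corner, model$fluct_cutoff)
  })
  # anchor the realization at the origin so trajectories start at (0, 0)
  if (length(fx)) fx <- fx - fx[1]
  if (length(fy)) fy <- fy - fy[1]
  data.frame(t = t,
             x = model$linear_rate[1] * t + fx,
             y = model$linear_rate[2] * t + fy)
}
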