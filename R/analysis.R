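#' RMS displacement about a setpoint
#'
#' @param trace Data.frame with columns `x`, `y` (a `tracked_trace` or any
#'   position series).
#' @param setpoint Reference position in nm (default `c(0, 0)`).
#' @return Named numeric `c(x = , y = )`: per-axis root-mean-square of
#'   (position - setpoint).
#' @export
rms_about <- function(trace, setpoint = c(0, 0)) {
  trace <- as.data.frame(trace)
  if (nrow(trace) == 0L) stop("empty trace")
  setpoint <- per_axis(setpoint, "setpoint")
  c(x = sqrt(mean((trace$x - setpoint[1])^2)),
    y = sqrt(mean((trace$y - setpoint[2])^2)))
}

#' Single-sided amplitude spectrum of a tracked trace
#'
#' Discrete Fourier transform scaled so that a pure sinusoid of amplitude A
#' produces a peak of height A at its frequency (2/N single-sided scaling;
#' rectangular window). The frequency resolution is 1/record duration.
#'
#' @param trace Data.frame with columns `t`, `x`, `y` sampled uniformly, or
#'   a numeric vector (then `rate` is required).
#' @param detrend `"none"` or `"mean"` (subtract the mean first).
#' @param rate Sample rate in Hz (inferred from `t` if omitted).
#' @return An `amplitude_spectrum`: data.frame with columns `frequency`
#'   (Hz) and the per-axis amplitudes (`x`, `y`, or `value` for a vector
#'   input), with attributes `record_duration` and `rate`. DC and the
#'   Nyquist bin are excluded.
#' @export
amplitude_spectrum <- function(trace, detrend = c("none", "mean"),
                               rate = NULL) {
  detrend <- match.arg(detrend)
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(rate)) stop("rate is required for a plain numeric input")
    series <- list(value = trace)
    n <- length(trace)
  } else {
    trace <- as.data.frame(trace)
    n <- nrow(trace)
    if (n < 2L) stop("trace too short")
    dt <- diff(trace$t)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("non-uniform timestamps: amplitude spectrum requires uniform sampling")
    if (is.null(rate)) rate <- 1 / dt[1]
    series <- list(x = trace$x, y = trace$y)
  }
  k <- seq_len(ceiling(n / 2) - 1L)        # positive frequencies below Nyquist
  out <- data.frame(frequency = k * rate / n)
  for (nm in names(series)) {
    z <- series[[nm]]
    if (detrend == "mean") z <- z - mean(z)
    amp <- 2 * Mod(stats::fft(z)[k + 1L]) / n
    out[[nm]] <- amp
  }
  structure(out, record_duration = n / rate, rate = rate,
            class = c("amplitude_spectrum", "data.frame"))
}

#' Per-position means and step sizes from a schedule
#'
#' Averages the trace over each scheduled collection window and returns the
#' sign-rectified successive differences of the window means -- the measured
#' step sizes of a back-and-forth step test.
#'
#' @param trace Data.frame with columns `t` and the position axes.
#' @param schedule Data.frame with columns `t_start`, `t_end`: one
#'   collection window per position, non-overlapping and increasing.
#' @param axis Which axis to difference (`"x"` or `"y"`).
#' @return List with `means` (per-window mean of the chosen axis), `n_used`
#'   (samples per window), and `step_sizes` (absolute successive
#'   differences).
#' @export
extract_steps <- function(trace, schedule, axis = c("x", "y")) {
  axis <- match.arg(axis)
  trace <- as.data.frame(trace)
  schedule <- as.data.frame(schedule)
  if (!all(c("t_start", "t_end") %in% names(schedule)))
    stop("schedule needs t_start and t_end columns")
  if (nrow(schedule) < 2L) stop("schedule needs at least two positions")
  if (any(schedule$t_end <= schedule$t_start))
    stop("schedule windows must have positive length")
  period <- stats::median(diff(trace$t))
  if (min(schedule$t_start) < min(trace$t) - 1e-9 ||
      max(schedule$t_end) > max(trace$t) + period + 1e-9)
    stop("schedule does not align with the trace time range")
  z <- trace[[axis]]
  means <- numeric(nrow(schedule))
  n_used <- integer(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    sel <- trace$t >= schedule$t_start[i] - 1e-12 &
           trace$t < schedule$t_end[i] - 1e-12
    if (!any(sel)) stop("schedule window contains no trace samples")
    means[i] <- mean(z[sel])
    n_used[i] <- sum(sel)
  }
  list(means = means, n_used = n_used, step_sizes = abs(diff(means)))
}

#' Effective low-pass cutoff of block averaging
#'
#' Averaging `n_averaged` consecutive values acquired at `rate` low-passes
#' the data to an effective cutoff of `rate / n_averaged` (43 Hz for 200
#' values at 8.6 kHz; 29.5 Hz for 200 values at 5.9 kHz).
#'
#' @param rate Acquisition rate in Hz.
#' @param n_averaged Number of averaged values (>= 1).
#' @return Cutoff frequency in Hz.
#' @export
effective_lowpass <- function(rate, n_averaged) {
  stop_if_not_scalar_pos(rate, "rate")
  if (!is.numeric(n_averaged) || length(n_averaged) != 1L || n_averaged < 1)
    stop("n_averaged must be >= 1")
  rate / n_averaged
}

#' Gaussian summary of measured step sizes
#'
#' Maximum-likelihood Gaussian fit of a step-size sample (equivalently the
#' sample mean and standard deviation) with the standard error of the mean.
#' Below 50 steps the sample statistics are returned with `gaussian = FALSE`
#' (too few for a meaningful histogram fit); grid-snapped stabilized
#' position histograms are discrete and should not be Gaussian-fit at all.
#'
#' @param step_sizes Numeric vector of step sizes (nm), length >= 2.
#' @return List with `mean`, `std`, `se_mean` (nm), `n`, and `gaussian`
#'   (logical: fit considered meaningful).
#' @export
fit_step_histogram <- function(step_sizes) {
  step_sizes <- as.numeric(step_sizes)
  if (length(step_sizes) < 2L) stop("need at least two steps")
  m <- mean(step_sizes)
  s <- stats::sd(step_sizes)
  list(mean = m, std = s, se_mean = s / sqrt(length(step_sizes)),
       n = length(step_sizes), gaussian = length(step_sizes) >= 50L)
}
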