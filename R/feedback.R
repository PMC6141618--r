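#' Feedback-loop configuration
#'
#' The stabilization loop runs pure integral action: at every loop tick the
#' displacement of the tracked position from the setpoint is measured and a
#' compensating increment `-gain * (tracked - setpoint)` is added to the
#' running stage command. The stage's own second-order dynamics low-pass the
#' commands. Gains are per axis; the default 0.2 gives an approximately
#' 190 Hz unity-gain crossover at the 5.9 kHz loop rate with a comfortable
#' phase margin against the 340 Hz stage resonance. Gains above roughly 0.3
#' lose the phase margin and ring or diverge (full compensation, gain 1, is
#' unstable with this stage); the documented stable range is (0, 0.25] --
#' see the methods vignette.
#'
#' @param setpoint Desired held position in nm (default `c(0, 0)`).
#' @param gain Per-axis integral gain in (0, 1] (default 0.2).
#' @param loop_rate Feedback rate in Hz (default 5900, the realized rate
#'   once tracking, correction, and stage polling are all done per tick).
#' @param block_size Detector samples averaged per tracked position
#'   (default 100; at 1 MHz digitization this is the 100-point average).
#' @param enabled `TRUE`, `FALSE`, or a function of time (s) returning
#'   whether feedback is active (a piecewise-constant schedule).
#' @return A `feedback_config` object.
#' @export
feedback_config <- function(setpoint = c(0, 0), gain = 0.2, loop_rate = 5900,
                            block_size = 100, enabled = TRUE) {
  setpoint <- per_axis(setpoint, "setpoint")
  gain <- per_axis(gain, "gain")
  if (any(gain <= 0 | gain > 1)) stop("gain must be in (0, 1]")
  stop_if_not_scalar_pos(loop_rate, "loop_rate")
  stop_if_not_scalar_pos(block_size, "block_size")
  if (!is.function(enabled) && !(is.logical(enabled) && length(enabled) == 1L))
    stop("enabled must be TRUE, FALSE, or a function of time")
  structure(list(setpoint = setpoint, gain = gain, loop_rate = loop_rate,
                 block_size = as.integer(block_size), enabled = enabled),
            class = "feedback_config")
}

#' Stage-command increment for one feedback tick
#'
#' @param tracked Tracked position in nm.
#' @param setpoint Setpoint in nm.
#' @param gain Per-axis gain.
#' @return The increment `-gain * (tracked - setpoint)` to add to the
#'   running commanded position (integral action).
#' @export
correction <- function(tracked, setpoint, gain = 0.2) {
  -per_axis(gain, "gain") * (per_axis(tracked, "tracked") -
                             per_axis(setpoint, "setpoint"))
}

#' Run the closed-loop stabilization simulation
#'
#' Per loop tick: acquire a block of detector samples at the fiducial's
#' current position (sample drift plus stage position), convert each sample
#' to a map index and look up its position, block-average to the tracked
#' position, then -- if feedback is enabled at that time -- apply the
#' integral correction to the stage command and advance the stage dynamics
#' through its servo substeps. The stage's reported (sensed) position is
#' polled every tick.
#'
#' @param model A [qapd_response_model()].
#' @param map A `contour_map` built over the expected excursion range.
#' @param config A [feedback_config()].
#' @param duration Run duration in s.
#' @param drift A [drift_model()] (default calibration).
#' @param stage A [stage_state()].
#' @param noise_rms Detector noise RMS per normalized sample (default 0.01).
#' @param seed Integer seed governing drift, detector and sensor noise.
#' @param setpoint_fn Optional function of time returning the setpoint (nm),
#'   overriding `config$setpoint` (used for setpoint step tests).
#' @param command_fn Optional function of time returning an open-loop stage
#'   command offset in nm (used for commanded step tests).
#' @return A `closed_loop_record`: list with data.frames `tracked`,
#'   `sensed`, `commanded` (columns `t`, `x`, `y`), `setpoint` (per tick),
#'   `enabled` (logical per tick), `config`, `loop_rate`, `misses`,
#'   `clamped_ticks`, and the drift trajectory used.
#' @export
run_closed_loop <- function(model, map, config = feedback_config(),
                            duration = 10, drift = drift_model(),
                            stage = stage_state(), noise_rms = 0.01,
                            seed = NULL, setpoint_fn = NULL,
                            command_fn = NULL) {
  stopifnot(inherits(model, "qapd_response_model"),
            inherits(map, "contour_map"),
            inherits(config, "feedback_config"),
            inherits(drift, "drift_model"),
            inherits(stage, "stage_state"))
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  fs <- config$loop_rate
  n <- round(duration * fs)
  if (n < 1) stop("duration too short for the loop rate")
  B <- config$block_size
  tab <- map_position_table(map)
  gain <- config$gain
  enabled_fn <- if (is.function(config$enabled)) config$enabled else
    local({e <- config$enabled; function(t) e})
  n_sub <- max(1L, round(stage$servo_rate / fs))
  t <- (seq_len(n) - 1L) / fs

  with_seed(seed, {
    dr <- make_drift(drift, duration, fs, seed = NULL)
    trk_x <- trk_y <- sen_x <- sen_y <- cmd_x <- cmd_y <- numeric(n)
    set_x <- set_y <- numeric(n)
    enab <- logical(n)
    misses <- 0L
    clamped_ticks <- 0L
    edge_run <- 0
    cmd <- c(0, 0)
    act <- stage$actual; vel <- stage$velocity
    Ad <- stage$Ad; Bd <- stage$Bd
    snr <- stage$sensor_noise_rms
    h0 <- tab$h0; dh <- tab$dh; v0 <- tab$v0; dv <- tab$dv
    nh <- tab$nh; nv <- tab$nv
    px <- tab$x; py <- tab$y; pmiss <- tab$miss
    for (k in seq_len(n)) {
      fx <- dr$x[k] + act[1]
      fy <- dr$y[k] + act[2]
      hs <- model$h_field(fx, fy) + stats::rnorm(B, sd = noise_rms)
      vs <- model$v_field(fx, fy) + stats::rnorm(B, sd = noise_rms)
      hi <- clamp(round((hs - h0) / dh), 0, nh - 1)
      vi <- clamp(round((vs - v0) / dv), 0, nv - 1)
      i1 <- hi * nv + vi + 1
      tracked <- c(sum(px[i1]), sum(py[i1])) / B
      misses <- misses + sum(pmiss[i1])
      trk_x[k] <- tracked[1]; trk_y[k] <- tracked[2]
      sp <- if (is.null(setpoint_fn)) config$setpoint else
        per_axis(setpoint_fn(t[k]), "setpoint")
      set_x[k] <- sp[1]; set_y[k] <- sp[2]
      on <- isTRUE(enabled_fn(t[k]))
      enab[k] <- on
      if (on) cmd <- cmd - gain * (tracked - sp)
      u <- cmd
      if (!is.null(command_fn)) u <- u + per_axis(command_fn(t[k]), "command")
      if (any(u < stage$travel[1] | u > stage$travel[2])) {
        clamped_ticks <- clamped_ticks + 1L
        u <- clamp(u, stage$travel[1], stage$travel[2])
      }
      for (s in seq_len(n_sub)) {
        a1 <- Ad[1, 1] * act[1] + Ad[1, 2] * vel[1] + Bd[1] * u[1]
        v1 <- Ad[2, 1] * act[1] + Ad[2, 2] * vel[1] + Bd[2] * u[1]
        a2 <- Ad[1, 1] * act[2] + Ad[1, 2] * vel[2] + Bd[1] * u[2]
        v2 <- Ad[2, 1] * act[2] + Ad[2, 2] * vel[2] + Bd[2] * u[2]
        act[1] <- a1; vel[1] <- v1; act[2] <- a2; vel[2] <- v2
      }
      if (snr > 0) {
        ns <- stats::rnorm(2, sd = snr)
        sen_x[k] <- act[1] + ns[1]; sen_y[k] <- act[2] + ns[2]
      } else {
        sen_x[k] <- act[1]; sen_y[k] <- act[2]
      }
      cmd_x[k] <- u[1]; cmd_y[k] <- u[2]
      # abort if the tracked position is pinned at the map edge for > 1 s
      # (pinned = nearly every sample quantized to an extreme level index)
      at_edge <- mean(hi == 0 | hi == nh - 1) > 0.9 ||
                 mean(vi == 0 | vi == nv - 1) > 0.9
      edge_run <- if (at_edge) edge_run + 1 else 0
      if (edge_run > fs) stop("fiducial left map: tracked position pinned at the map edge for > 1 s")
    }
  })
  structure(list(
    tracked = structure(data.frame(t = t, x = trk_x, y = trk_y),
                        nominal_rate = fs, block_size = B, misses = misses,
                        class = c("tracked_trace", "data.frame")),
    sensed = data.frame(t = t, x = sen_x, y = sen_y),
    commanded = data.frame(t = t, x = cmd_x, y = cmd_y),
    setpoint = data.frame(t = t, x = set_x, y = set_y),
    enabled = enab, config = config, loop_rate = fs, misses = misses,
    clamped_ticks = clamped_ticks, drift_trajectory = dr),
    class = "closed_loop_record")
}

#' @export
print.closed_loop_record <- function(x, ...) {
  cat(sprintf("Closed-loop record: %.3g s at %g Hz (%d ticks)\n",
              nrow(x$tracked) / x$loop_rate, x$loop_rate, nrow(x$tracked)))
  on <- mean(x$enabled)
  cat(sprintf("  feedback on %.0f%% of ticks; %d placeholder lookups; %d clamped ticks\n",
              100 * on, x$misses, x$clamped_ticks))
  if (any(x$enabled)) {
    sel <- x$enabled
    r <- sqrt(c(mean((x$tracked$x[sel] - x$setpoint$x[sel])^2),
                mean((x$tracked$y[sel] - x$setpoint$y[sel])^2)))
    cat(sprintf("  RMS about setpoint while on: %.3f nm (X), %.3f nm (Y)\n",
                r[1], r[2]))
  }
  invisible(x)
}

#' Step test of tracking and feedback
#'
#' Alternates a commanded displacement of `step_nm` back and forth along one
#' axis: with `feedback_on = FALSE` the stage itself is commanded to step
#' (tracking follows open loop); with `feedback_on = TRUE` the feedback
#' setpoint is stepped instead and the loop drives the stage. At each
#' position the loop dwells `dwell` seconds (17 ms by default) and then
#' `samples_per_position` tracked and stage-sensor values are collected and
#' averaged. Step sizes are the sign-rectified successive differences of the
#' per-position means; accuracy is the deviation of the mean step from the
#' commanded step and precision is the step-size standard deviation.
#'
#' @inheritParams run_closed_loop
#' @param axis `"x"` or `"y"`.
#' @param step_nm Commanded step in nm (the benchmark set is 0, 2, 4, 6, 8,
#'   10, 20).
#' @param n_positions Number of dwell positions (>= 2).
#' @param samples_per_position Tracked values averaged per position.
#' @param feedback_on Step the setpoint (TRUE) or the stage command (FALSE).
#' @param dwell Settling wait per position in s before collection
#'   (default 0.017). A dwell shorter than the stage settling time
#'   (10 / resonant frequency) is recorded in `warnings`.
#' @return A `step_test_result`: list with `step_sizes` (nm), `mean`, `std`,
#'   `accuracy` (|mean - commanded|), `precision` (= std), `sensed_steps`,
#'   `position_means`, `gaussian_fit` (from [fit_step_histogram()] when
#'   `n_positions >= 50`), `commanded`, `axis`, `n_positions`,
#'   `samples_per_position`, `feedback_on`, `warnings`, and the full
#'   `record`.
#' @export
run_step_test <- function(model, map, axis = c("x", "y"), step_nm = 4,
                          n_positions = 250, samples_per_position = 200,
                          feedback_on = TRUE, dwell = 0.017,
                          config = feedback_config(),
                          drift = drift_model(), stage = stage_state(),
                          noise_rms = 0.01, seed = NULL) {
  axis <- match.arg(axis)
  if (!step_nm %in% c(0, 2, 4, 6, 8, 10, 20))
    stop("step_nm must be one of 0, 2, 4, 6, 8, 10, 20")
  if (n_positions < 2) stop("n_positions must be >= 2")
  warnings <- character(0)
  settle <- 10 / stage$resonant_freq
  if (dwell < settle)
    warnings <- c(warnings, sprintf(
      "dwell %.3g s is shorter than the stage settling time %.3g s",
      dwell, settle))
  fs <- if (feedback_on) config$loop_rate else 8600
  cfg <- feedback_config(setpoint = config$setpoint, gain = config$gain,
                         loop_rate = fs, block_size = config$block_size,
                         enabled = feedback_on)
  period <- dwell + samples_per_position / fs
  total <- n_positions * period
  # position p (0-based) active on t in [p*period, (p+1)*period); offset
  # alternates 0, step, 0, step, ...
  offset_at <- function(t) {
    p <- pmin(floor(t / period), n_positions - 1)
    (p %% 2) * step_nm
  }
  step_vec <- function(o) if (axis == "x") c(o, 0) else c(0, o)
  rec <- run_closed_loop(
    model, map, cfg, duration = total, drift = drift, stage = stage,
    noise_rms = noise_rms, seed = seed,
    setpoint_fn = if (feedback_on)
      function(t) cfg$setpoint + step_vec(offset_at(t)) else NULL,
    command_fn = if (!feedback_on)
      function(t) step_vec(offset_at(t)) else NULL)
  sched <- data.frame(
    t_start = (seq_len(n_positions) - 1L) * period + dwell,
    t_end = seq_len(n_positions) * period)
  steps <- extract_steps(rec$tracked, sched, axis = axis)
  sensed_steps <- extract_steps(rec$sensed, sched, axis = axis)
  gfit <- if (n_positions >= 50) fit_step_histogram(steps$step_sizes) else NULL
  res <- list(step_sizes = steps$step_sizes, mean = mean(steps$step_sizes),
              std = stats::sd(steps$step_sizes),
              accuracy = abs(mean(steps$step_sizes) - step_nm),
              precision = stats::sd(steps$step_sizes),
              sensed_steps = sensed_steps$step_sizes,
              position_means = steps$means,
              gaussian_fit = gfit, commanded = step_nm, axis = axis,
              n_positions = n_positions,
              samples_per_position = samples_per_position,
              feedback_on = feedback_on, warnings = warnings, record = rec)
  class(res) <- "step_test_result"
  res
}

#' @export
print.step_test_result <- function(x, ...) {
  cat(sprintf("Step test: %s axis, %g nm commanded, %d positions x %d samples, feedback %s\n",
              toupper(x$axis), x$commanded, x$n_positions,
              x$samples_per_position, if (x$feedback_on) "on" else "off"))
  cat(sprintf("  measured step: %.4f +/- %.4f nm (mean +/- sd of %d steps)\n",
              x$mean, x$std, length(x$step_sizes)))
  cat(sprintf("  accuracy: %.1f pm, precision: %.1f pm\n",
              1000 * x$accuracy, 1000 * x$precision))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
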