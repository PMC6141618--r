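#' Simulated piezo stage
#'
#' The stage mechanics are a second-order low-pass: the actual position
#' follows the commanded position through
#' \deqn{\ddot p = \omega_0^2 (u - p) - 2 \zeta \omega_0 \dot p,}
#' with resonant frequency \eqn{f_0 = \omega_0 / 2\pi} (340 Hz by default,
#' the stiffness limit of the stage) and damping ratio \eqn{\zeta}. The
#' internal servo updates at `servo_rate` (20 kHz); each servo step applies
#' the exact zero-order-hold discretization of the continuous dynamics. The
#' sensed position is the actual position plus zero-mean capacitive-sensor
#' noise.
#'
#' @param pos Initial position in nm (commanded = actual = sensed).
#' @param resonant_freq Mechanical resonance in Hz (default 340).
#' @param damping_ratio Dimensionless damping (default 0.5).
#' @param servo_rate Servo update rate in Hz (default 20000).
#' @param sensor_noise_rms Position-sensor noise RMS in nm (default 0.1).
#' @param travel Per-axis travel limits in nm, `c(min, max)` (default
#'   +/- 5000). Commands outside are clamped and flagged.
#' @return An object of class `stage_state` holding `commanded`, `actual`,
#'   `velocity`, `sensed` (each length-2, nm), the parameters, and the
#'   precomputed discrete state-transition coefficients.
#' @seealso [step_stage()]
#' @export
stage_state <- function(pos = c(0, 0), resonant_freq = 340,
                        damping_ratio = 0.5, servo_rate = 20000,
                        sensor_noise_rms = 0.1, travel = c(-5000, 5000)) {
  pos <- per_axis(pos, "pos")
  stop_if_not_scalar_pos(resonant_freq, "resonant_freq")
  stop_if_not_scalar_pos(damping_ratio, "damping_ratio")
  stop_if_not_scalar_pos(servo_rate, "servo_rate")
  if (sensor_noise_rms < 0) stop("sensor_noise_rms must be >= 0")
  travel <- as.numeric(travel)
  if (length(travel) != 2L || travel[2] <= travel[1])
    stop("travel must be c(min, max)")
  disc <- .stage_discretize(resonant_freq, damping_ratio, 1 / servo_rate)
  structure(list(commanded = pos, actual = pos, velocity = c(0, 0),
                 sensed = pos, resonant_freq = resonant_freq,
                 damping_ratio = damping_ratio, servo_rate = servo_rate,
                 sensor_noise_rms = sensor_noise_rms, travel = travel,
                 clamped = FALSE, Ad = disc$Ad, Bd = disc$Bd),
            class = "stage_state")
}

# Exact ZOH discretization of [p; v]' = A [p; v] + B u over dt, using the
# closed-form matrix exponential of the second-order system (under-, crit-,
# and over-damped branches).
.stage_discretize <- function(f0, zeta, dt) {
  w0 <- 2 * pi * f0
  A <- matrix(c(0, -w0^2, 1, -2 * zeta * w0), 2, 2)
  B <- c(0, w0^2)
  a <- exp(-zeta * w0 * dt)
  if (abs(zeta - 1) < 1e-12) {
    Ad <- a * matrix(c(1 + w0 * dt, -w0^2 * dt, dt, 1 - w0 * dt), 2, 2)
  } else if (zeta < 1) {
    wd <- w0 * sqrt(1 - zeta^2)
    cs <- cos(wd * dt); sn <- sin(wd * dt)
    Ad <- a * matrix(c(cs + zeta * w0 / wd * sn, -(w0^2 / wd) * sn,
                       sn / wd, cs - zeta * w0 / wd * sn), 2, 2)
  } else {
    wd <- w0 * sqrt(zeta^2 - 1)
    cs <- cosh(wd * dt); sn <- sinh(wd * dt)
    Ad <- a * matrix(c(cs + zeta * w0 / wd * sn, -(w0^2 / wd) * sn,
                       sn / wd, cs - zeta * w0 / wd * sn), 2, 2)
  }
  Bd <- solve(A, (Ad - diag(2)) %*% B)
  list(Ad = Ad, Bd = as.numeric(Bd))
}

#' Advance the stage by one servo step
#'
#' @param state A [stage_state()].
#' @param command Commanded position in nm, length 2. Commands outside the
#'   travel range are clamped and the returned state's `clamped` flag set.
#' @param dt Time step in s; must equal `1/servo_rate`.
#' @param sensor_noise If `FALSE`, the sensed position is the exact actual
#'   position (useful for deterministic tests).
#' @return The advanced `stage_state`.
#' @export
step_stage <- function(state, command, dt = 1 / state$servo_rate,
                       sensor_noise = TRUE) {
  stopifnot(inherits(state, "stage_state"))
  command <- per_axis(command, "command")
  if (abs(dt - 1 / state$servo_rate) > 1e-12)
    stop("dt must equal 1/servo_rate")
  clamped <- any(command < state$travel[1] | command > state$travel[2])
  command <- clamp(command, state$travel[1], state$travel[2])
  for (ax in 1:2) {
    s <- state$Ad %*% c(state$actual[ax], state$velocity[ax]) +
      state$Bd * command[ax]
    state$actual[ax] <- s[1]
    state$velocity[ax] <- s[2]
  }
  noise <- if (sensor_noise && state$sensor_noise_rms > 0)
    stats::rnorm(2, sd = state$sensor_noise_rms) else c(0, 0)
  state$sensed <- state$actual + noise
  state$commanded <- command
  state$clamped <- clamped
  state
}
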