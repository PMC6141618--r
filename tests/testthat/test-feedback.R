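test_that("the integral correction law compensates measured displacement", {
  expect_equal(correction(c(5, 5), c(5, 5), 1), c(0, 0))
  expect_equal(correction(c(7, 2), c(5, 5), 1), c(-2, 3))
  # constant disturbance on a static plant: geometric convergence with
  # ratio (1 - g)
  g <- 0.3; d <- c(2, -3)
  cmd <- c(0, 0)
  errs <- numeric(20)
  for (k in 1:20) {
    tracked <- d + cmd
    errs[k] <- tracked[1]
    cmd <- cmd + correction(tracked, c(0, 0), g)
  }
  expect_equal(errs, d[1] * (1 - g)^(0:19), tolerance = 1e-12)
})

test_that("a quiet loop tracking at the setpoint issues no corrections", {
  m <- default_model()
  map <- default_map()
  # setpoint on an exact map grid point, fiducial starting there
  dec <- unpack_entry(map$entries, map$region)
  k <- which(!is.na(dec$x))
  k0 <- k[which.min(dec$x[k]^2 + dec$y[k]^2)]
  sp <- c(dec$x[k0], dec$y[k0])
  rec <- run_closed_loop(
    m, map, feedback_config(setpoint = sp), duration = 0.05,
    drift = drift_model(linear_rate = c(0, 0), fluct_amplitude = c(0, 0)),
    stage = stage_state(pos = sp, sensor_noise_rms = 0), noise_rms = 0,
    command_fn = function(t) sp, seed = 1)
  # tracked sits on the setpoint, so the integral never moves
  expect_lt(max(abs(rec$tracked$x - sp[1])), 1e-9)
  expect_lt(max(abs(rec$tracked$y - sp[2])), 1e-9)
  expect_lt(max(abs(rec$commanded$x - sp[1])), 1e-9)
  expect_lt(max(abs(rec$sensed$x - sp[1])), 1e-9)
})

test_that("open-loop tracking passes the injected drift through", {
  m <- default_model()
  map <- default_map()
  dm <- drift_model(linear_rate = c(2, -1), fluct_amplitude = c(1, 1))
  rec <- run_closed_loop(m, map, feedback_config(enabled = FALSE),
                         duration = 2, drift = dm,
                         stage = stage_state(sensor_noise_rms = 0),
                         noise_rms = 0, seed = 3)
  dr <- rec$drift_trajectory
  n <- nrow(rec$tracked)
  expect_lt(max(abs(rec$tracked$x - dr$x[seq_len(n)])), 0.45)
  expect_lt(max(abs(rec$tracked$y - dr$y[seq_len(n)])), 0.45)
})

test_that("the loop is stable across its documented gain range", {
  m <- default_model()
  map <- default_map()
  dm <- drift_model(linear_rate = c(10, 5), fluct_amplitude = c(2, 2))
  for (g in c(0.05, 0.15, 0.25)) {
    rec <- run_closed_loop(m, map, feedback_config(gain = g), duration = 0.6,
                           drift = dm, noise_rms = 0.01, seed = 5)
    expect_lt(max(abs(rec$commanded$x)), 50)
    expect_lt(max(abs(rec$commanded$y)), 50)
    # held near the setpoint once the loop has spun up
    late <- rec$tracked$t > 0.2
    expect_lt(sqrt(mean(rec$tracked$x[late]^2)), 0.5)
  }
})

test_that("feedback toggling hands off between stage and drift continuously", {
  m <- default_model()
  map <- default_map()
  sched <- function(t) t < 2
  rec <- run_closed_loop(m, map, feedback_config(enabled = sched),
                         duration = 4, drift = drift_model(), seed = 11)
  # the reconstructed drift (tracked displacement minus stage correction)
  # must not jump across the toggle; subtracting the continuous injected
  # drift isolates any handoff discontinuity from the drift's own motion
  n <- nrow(rec$tracked)
  err <- (rec$tracked$x - rec$sensed$x) - rec$drift_trajectory$x[seq_len(n)]
  k <- max(which(rec$enabled))
  before <- mean(err[(k - 29):k])
  after <- mean(err[(k + 1):(k + 30)])
  grid_step <- (map$region[2] - map$region[1]) / (map$h_levels$n_levels - 1)
  expect_lt(abs(after - before), grid_step)
  # commanded position stays frozen once feedback is off
  off <- which(!rec$enabled)
  expect_equal(length(unique(rec$commanded$x[off])), 1)
})

test_that("aborts when the fiducial leaves the map", {
  m <- default_model()
  map <- default_map()
  runaway <- drift_model(linear_rate = c(60, 0), fluct_amplitude = c(0, 0))
  expect_error(
    run_closed_loop(m, map, feedback_config(enabled = FALSE), duration = 3,
                    drift = runaway, noise_rms = 0, seed = 1),
    "left map")
})

test_that("step tests recover commanded steps and record dwell warnings", {
  m <- default_model()
  map <- default_map()
  quiet_drift <- drift_model(linear_rate = c(0, 0), fluct_amplitude = c(0, 0))
  # noiseless feedback-off stepping: the sensed stage channel reproduces the
  # commanded step exactly once settled
  st <- run_step_test(m, map, axis = "x", step_nm = 4, n_positions = 6,
                      samples_per_position = 50, feedback_on = FALSE,
                      dwell = 0.03, drift = quiet_drift,
                      stage = stage_state(sensor_noise_rms = 0),
                      noise_rms = 0, seed = 2)
  expect_length(st$sensed_steps, 5)
  expect_equal(st$sensed_steps, rep(4, 5), tolerance = 1e-6)
  expect_length(st$warnings, 0)

  # a null step with feedback measures ~zero within noise
  s0 <- run_step_test(m, map, axis = "x", step_nm = 0, n_positions = 10,
                      samples_per_position = 100, feedback_on = TRUE,
                      seed = 3)
  expect_lt(s0$mean, 0.25)   # zero within tracker noise (half a grid step)
  expect_match(s0$warnings, "settling")

  expect_error(run_step_test(m, map, step_nm = 3), "step_nm")
  expect_error(run_step_test(m, map, n_positions = 1), "n_positions")
})
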