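test_that("detector response is centered, antisymmetric, and monotone", {
  m <- default_model()
  r0 <- evaluate_response(m, c(0, 0))
  expect_equal(r0$h_norm, 0)
  expect_equal(r0$v_norm, 0)
  expect_gt(r0$total, 0)

  set.seed(11)
  pts <- cbind(runif(50, -80, 80), runif(50, -80, 80))
  rp <- evaluate_response(m, pts)
  rn <- evaluate_response(m, -pts)
  expect_equal(rn$h_norm, -rp$h_norm, tolerance = 1e-12)
  expect_equal(rn$v_norm, -rp$v_norm, tolerance = 1e-12)

  xs <- seq(-50, 50, length.out = 101)
  h_line <- evaluate_response(m, cbind(xs, 0))$h_norm
  expect_true(all(diff(h_line) > 0))
  v_line <- evaluate_response(m, cbind(0, xs))$v_norm
  expect_true(all(diff(v_line) > 0))

  expect_error(evaluate_response(m, c(5000, 0)), "domain")
})

test_that("sample streams reduce to the noiseless response and reproduce noise", {
  m <- default_model()
  s0 <- sample_stream(m, c(10, -5), duration = 1e-4, noise_rms = 0)
  ref <- evaluate_response(m, c(10, -5))
  expect_equal(nrow(s0), 100)
  expect_true(all(s0$h_norm == ref$h_norm))
  expect_true(all(s0$v_norm == ref$v_norm))

  s1 <- sample_stream(m, c(0, 0), duration = 1, noise_rms = 0.02, seed = 4)
  expect_equal(nrow(s1), 1e6)
  expect_lt(abs(sd(s1$h_norm) / 0.02 - 1), 0.01)
  s2 <- sample_stream(m, c(0, 0), duration = 1, noise_rms = 0.02, seed = 4)
  expect_identical(s1, s2)

  expect_error(sample_stream(m, c(0, 0), duration = 1e-4, noise_rms = -1))
  expect_error(sample_stream(m, data.frame(t = numeric(0), x = numeric(0),
                                           y = numeric(0))))
})

test_that("drift trajectories follow the ramp-plus-band-limited model", {
  dz <- drift_model(linear_rate = c(0, 0), fluct_amplitude = c(0, 0))
  tr <- make_drift(dz, 1, 100)
  expect_true(all(tr$x == 0) && all(tr$y == 0))

  dr <- drift_model(linear_rate = c(1, 0), fluct_amplitude = c(0, 0))
  tr <- make_drift(dr, 10, 100)
  expect_equal(tr$x[nrow(tr)], 10, tolerance = 1e-12)
  expect_equal(tr$y[nrow(tr)], 0)

  expect_error(make_drift(dz, -1, 100))
  # reproducibility from the model seed
  ds <- drift_model(seed = 99)
  expect_identical(make_drift(ds, 1, 500), make_drift(ds, 1, 500))
})

test_that("default drift calibration gives tens-of-nm 10 s excursions", {
  dm <- drift_model()
  pp <- t(vapply(1:100, function(s) {
    tr <- make_drift(dm, 10, 200, seed = s)
    c(diff(range(tr$x)), diff(range(tr$y)))
  }, numeric(2)))
  expect_gt(mean(pp[, 1]), 10)
  expect_lt(mean(pp[, 1]), 55)
  expect_lt(mean(pp[, 2]), 35)
})

test_that("drift power is confined below the spectral cutoff", {
  dm <- drift_model(linear_rate = c(0, 0))
  for (s in 1:5) {
    tr <- make_drift(dm, 10, 1000, seed = s)
    spec <- amplitude_spectrum(tr, detrend = "mean")
    p_below <- sum(spec$x[spec$frequency <= dm$fluct_cutoff]^2)
    expect_gte(p_below / sum(spec$x^2), 0.95)
  }
})

test_that("stage dynamics match second-order step-response theory", {
  st <- stage_state(sensor_noise_rms = 0)
  # fixed point: command equal to current actual leaves the state unchanged
  st2 <- step_stage(st, c(0, 0))
  expect_equal(st2$actual, c(0, 0))
  expect_equal(st2$velocity, c(0, 0))

  # unit step: settles within 1% after 10 / f0 seconds
  n_settle <- ceiling(10 / st$resonant_freq * st$servo_rate)
  s <- st
  peak <- 0
  for (k in seq_len(n_settle)) {
    s <- step_stage(s, c(1, 0))
    peak <- max(peak, s$actual[1])
  }
  expect_lt(abs(s$actual[1] - 1), 0.01)
  # overshoot for damping ratio 0.5: exp(-pi * z / sqrt(1 - z^2)) ~ 16.3%
  theory <- exp(-pi * 0.5 / sqrt(1 - 0.25))
  expect_equal(peak - 1, theory, tolerance = 0.01)

  # command clamped outside travel and flagged
  s3 <- step_stage(st, c(1e6, 0))
  expect_true(s3$clamped)
  expect_equal(s3$commanded[1], st$travel[2])
})

test_that("raster rendering conserves emitter counts and image geometry", {
  # 1.8 um x 1.8 um at 60 nm pixels is a 30 x 30 image
  ef <- emitter_field(matrix(c(0, 0), ncol = 2), background = 0)
  im <- render_raster(ef, c(-900, 900, -900, 900), pixel = 60,
                      shot_noise = FALSE)
  expect_equal(dim(im), c(30, 30))

  # an emitter at a pixel center puts the maximum at that pixel
  e2 <- emitter_field(matrix(c(-900 + 10.5 * 60, -900 + 7.5 * 60), ncol = 2),
                      background = 0)
  im2 <- render_raster(e2, c(-900, 900, -900, 900), pixel = 60,
                       shot_noise = FALSE)
  peak <- which(unclass(im2) == max(im2), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 11))

  # total noiseless counts = brightness * dwell within 0.5% on a >= 6 sigma field
  e3 <- emitter_field(matrix(c(10, -20), ncol = 2), brightness = 1e4,
                      psf_sigma = 100, background = 0)
  im3 <- render_raster(e3, c(-660, 660, -660, 660), pixel = 60,
                       dwell = 2e-3, shot_noise = FALSE)
  expect_equal(sum(im3) / (1e4 * 2e-3), 1, tolerance = 0.005)

  expect_error(render_raster(e3, c(-660, 660, -660, 660), pixel = -1))
  expect_error(render_raster(e3, c(-660, 660, -660, 660), dwell = 0))

  # shot noise is reproducible from the seed
  a <- render_raster(e3, c(-660, 660, -660, 660), seed = 3)
  b <- render_raster(e3, c(-660, 660, -660, 660), seed = 3)
  expect_identical(unclass(a), unclass(b))
})
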