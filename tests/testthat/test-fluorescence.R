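test_that("2D Gaussian fits localize noiseless emitters to sub-millipixel", {
  # emitter placed at the center of pixel column 13.8, row 10.2 (pixel-index
  # coordinates: pixel i spans [i-1, i] with center i - 0.5)
  target <- c(-900 + 13.3 * 60, -900 + 9.7 * 60)
  ef <- emitter_field(matrix(target, ncol = 2), background = 10)
  im <- render_raster(ef, c(-900, 900, -900, 900), pixel = 60,
                      dwell = 3e-3, shot_noise = FALSE)
  f <- fit_gaussian_2d(im)
  expect_true(f$converged)
  expect_lt(abs(f$centroid_px[["x"]] - 13.8), 1e-3)
  expect_lt(abs(f$centroid_px[["y"]] - 10.2), 1e-3)
  expect_equal(unname(f$centroid), target, tolerance = 0.1)
})

test_that("reported centroid errors match observed scatter", {
  ef <- emitter_field(matrix(c(0, 0), ncol = 2), background = 20)
  cents <- matrix(NA_real_, 100, 2)
  ses <- matrix(NA_real_, 100, 2)
  for (s in 1:100) {
    im <- render_raster(ef, c(-900, 900, -900, 900), pixel = 60,
                        dwell = 3e-3, seed = s)
    f <- fit_gaussian_2d(im)
    cents[s, ] <- f$centroid
    ses[s, ] <- f$centroid_se
  }
  for (ax in 1:2) {
    ratio <- sd(cents[, ax]) / mean(ses[, ax])
    expect_gt(ratio, 1 / 1.5)
    expect_lt(ratio, 1.5)
  }
})

test_that("degenerate images take the non-convergence path", {
  flat <- matrix(5, 20, 20)
  f <- fit_gaussian_2d(flat)
  expect_false(f$converged)
  expect_error(fit_gaussian_2d(flat, window = c(1, 3, 1, 3)), "5x5")
})

test_that("apex localization agrees across detection channels", {
  tip <- simulate_tip_images(center = c(30, -50), seed = 5)
  ap <- localize_apex(tip$backscatter, tip$luminescence)
  expect_true(ap$agreement)
  expect_equal(unname(ap$position), c(30, -50), tolerance = 15)

  # a backscatter spot offset by 2 sigma must break the agreement
  tip2 <- simulate_tip_images(center = c(0, 0), shot_noise = FALSE)
  off <- simulate_tip_images(center = c(0, 0) + 2 * 150, shot_noise = FALSE)
  ap2 <- localize_apex(off$backscatter, tip2$luminescence)
  expect_false(ap2$agreement)

  flat <- structure(matrix(1, 30, 30), region = c(-900, 900, -900, 900),
                    pixel = 60, class = c("raster_image", "matrix", "array"))
  expect_error(localize_apex(flat, flat), "no spot")

  agree <- vapply(1:50, function(s) {
    tp <- simulate_tip_images(center = c(10, 20), seed = s)
    localize_apex(tp$backscatter, tp$luminescence)$agreement
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("localization is translation-equivariant under whole-pixel shifts", {
  ef <- random_emitter_field(3, region = c(-500, 500, -500, 500),
                             min_separation = 500, seed = 14)
  reg <- c(-1200, 1200, -1200, 1200)  # wide margins keep fit windows interior
  im <- render_raster(ef, reg, pixel = 60, dwell = 3e-3, seed = 15)
  # shift the pixel data itself by (+2, +3) px, refilling with background
  shifted <- unclass(im)
  shifted <- rbind(matrix(median(im), 3, ncol(shifted)),
                   shifted[1:(nrow(shifted) - 3), ])
  shifted <- cbind(matrix(median(im), nrow(shifted), 2),
                   shifted[, 1:(ncol(shifted) - 2)])
  shifted <- structure(shifted, region = reg, pixel = 60,
                       class = class(im))
  a <- fidustab:::.fit_all_spots(im)
  b <- fidustab:::.fit_all_spots(shifted)
  a <- a[order(a$x_px), ]; b <- b[order(b$x_px), ]
  expect_equal(b$x_px, a$x_px + 2, tolerance = 1e-8)
  expect_equal(b$y_px, a$y_px + 3, tolerance = 1e-8)
})

test_that("spot detection conserves well-separated emitter counts", {
  ef <- random_emitter_field(6, region = c(-1200, 1200, -1200, 1200),
                             min_separation = 500, seed = 16)
  im <- render_raster(ef, c(-1500, 1500, -1500, 1500), pixel = 60,
                      dwell = 3e-3, seed = 17)
  expect_equal(nrow(detect_spots(im)), 6)
})

test_that("centroid drift measurement recovers injected shifts", {
  reg <- c(-1500, 1500, -1500, 1500)
  ef <- random_emitter_field(8, region = c(-1200, 1200, -1200, 1200),
                             min_separation = 800, seed = 3)
  img1 <- render_raster(ef, reg, pixel = 60, dwell = 3e-3, shot_noise = FALSE)
  # identical images: zero displacement
  d0 <- measure_drift(img1, img1)
  expect_equal(unname(d0$mean_displacement), c(0, 0), tolerance = 1e-9)
  expect_equal(d0$n_matched, 8)

  # eight noiseless emitters shifted by the benchmark (4.9, 3.02) px
  shift <- c(4.9, 3.02) * 60
  ef2 <- emitter_field(sweep(ef$positions, 2, -shift),
                       brightness = ef$brightness, psf_sigma = ef$psf_sigma,
                       background = ef$background)
  img2 <- render_raster(ef2, reg, pixel = 60, dwell = 3e-3,
                        shot_noise = FALSE)
  dm <- measure_drift(img1, img2)
  expect_equal(unname(dm$mean_displacement), c(4.9, 3.02), tolerance = 0.005)

  # eleven noisy emitters, small shift (0.4, 0.06) px, within 0.1 px
  ef11 <- random_emitter_field(11, region = c(-1300, 1300, -1300, 1300),
                               min_separation = 700, seed = 11)
  small <- c(0.4, 0.06) * 60
  ef11b <- emitter_field(sweep(ef11$positions, 2, -small),
                         brightness = ef11$brightness,
                         psf_sigma = ef11$psf_sigma,
                         background = ef11$background)
  i1 <- render_raster(ef11, reg, pixel = 60, dwell = 0.01, seed = 21)
  i2 <- render_raster(ef11b, reg, pixel = 60, dwell = 0.01, seed = 22)
  dsm <- measure_drift(i1, i2)
  expect_lt(max(abs(dsm$mean_displacement - c(0.4, 0.06))), 0.1)

  expect_error(measure_drift(img1, img2, matching_radius = 0.01), "matches")
})
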