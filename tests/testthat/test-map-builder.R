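test_that("contour levels evenly span the image range", {
  expect_equal(compute_levels(matrix(c(-1, 0.2, 1, 0.5), 2), 3)$levels,
               c(-1, 0, 1))
  lv <- compute_levels(matrix(c(-0.8, 0.8, 0, 0.1), 2), 200)
  expect_equal(unique(round(diff(lv$levels), 12)), round(1.6 / 199, 12))

  set.seed(21)
  for (i in 1:10) {
    img <- matrix(rnorm(64), 8)
    n <- sample(2:300, 1)
    lv <- compute_levels(img, n)
    expect_length(lv$levels, n)
    expect_equal(lv$levels[1], min(img))
    expect_equal(lv$levels[n], max(img))
    expect_lt(max(abs(diff(lv$levels) - lv$spacing)), 1e-12)
  }

  expect_error(compute_levels(matrix(1, 4, 4), 10), "constant")
  expect_error(compute_levels(matrix(rnorm(16), 4), 1))
})

test_that("contour extraction recovers closed-form lines of linear fields", {
  pair <- linear_scan_pair()
  reg <- pair$region
  # h = x / 50: level 0 -> the line x = 0
  c0 <- extract_contour(pair$h_image, reg, 0)[[1]]
  expect_gt(length(c0), 0)
  expect_lt(max(abs(unlist(lapply(c0, function(p) p[, "x"])))), 1e-6)
  # level 0.5 * max -> vertical line at x = 25 nm
  c5 <- extract_contour(pair$h_image, reg, 0.5)[[1]]
  expect_lt(max(abs(unlist(lapply(c5, function(p) p[, "x"])) - 25)), 1e-6)
  # tilted plane (x + y) / 100 at level 0 -> the diagonal y = -x
  xs <- pair$xs
  tilted <- outer(xs, xs, function(y, x) (x + y) / 100)
  ct <- extract_contour(tilted, reg, 0)[[1]]
  dev <- unlist(lapply(ct, function(p) p[, "x"] + p[, "y"]))
  expect_lt(max(abs(dev)), 1e-6)
  # level outside the image range -> no polylines
  expect_length(extract_contour(pair$h_image, reg, 2)[[1]], 0)
})

test_that("orthogonal linear fields intersect on the exact grid", {
  pair <- linear_scan_pair()
  hc <- extract_contour(pair$h_image, pair$region, c(-1, 0, 1))
  vc <- extract_contour(pair$v_image, pair$region, c(-1, 0, 1))
  inter <- find_intersections(hc, vc, pair$region)
  expect_false(anyNA(inter$x))
  grid <- c(-50, 0, 50)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(inter$x[i, j], grid[i], tolerance = 1e-6)
    expect_equal(inter$y[i, j], grid[j], tolerance = 1e-6)
  }

  # disjoint polylines yield an encoded absence, not an error
  h_only <- list(list(cbind(x = c(10, 10), y = c(0, 40))))
  v_only <- list(list(cbind(x = c(0, 40), y = c(-20, -20))))
  res <- find_intersections(h_only, v_only, pair$region)
  expect_true(is.na(res$x[1, 1]))
})

test_that("packing quantizes losslessly to sub-pm accuracy", {
  r <- c(0, 100, 0, 100)
  expect_identical(pack_entry(c(0, 0), r), 0)
  # the far corner clamps each axis code to 65534: 0xFFFEFFFE
  expect_identical(pack_entry(c(100, 100), r), 65534 * 65536 + 65534)
  expect_true(pack_entry(c(100, 100), r) < PLACEHOLDER)

  set.seed(31)
  pos <- cbind(runif(1e4, 0, 100), runif(1e4, 0, 100))
  back <- unpack_entry(pack_entry(pos, r), r)
  expect_lt(max(abs(back$x - pos[, 1])), 8e-4)   # 0.8 pm per axis
  expect_lt(max(abs(back$y - pos[, 2])), 8e-4)

  expect_error(pack_entry(c(101, 0), r), "outside")
  dec <- unpack_entry(PLACEHOLDER, r)
  expect_true(is.na(dec$x) && is.na(dec$y))
})

test_that("linear-field maps equal the analytic grid", {
  pair <- linear_scan_pair()
  map5 <- build_map(pair, 5)
  expect_length(map5$entries, 25)
  expect_equal(map5$build_metadata$placeholder_count, 0)
  dec <- unpack_entry(map5$entries, map5$region)
  grid <- seq(-50, 50, by = 25)
  packq <- 100 / 65535  # one code step
  expect_lt(max(abs(dec$x - rep(grid, each = 5))), packq)
  expect_lt(max(abs(dec$y - rep(grid, times = 5))), packq)

  # 200 levels over a 100 nm span: mean intersection spacing ~0.5 nm
  map200 <- build_map(pair, 200)
  expect_equal(map200$build_metadata$mean_nn_spacing, 0.5, tolerance = 0.02)
})

test_that("the default-response map is well formed", {
  map <- default_map()
  expect_length(map$entries, 40000)
  expect_lt(map$build_metadata$placeholder_fraction, 0.2)
  # every non-placeholder entry decodes to a position inside the region
  dec <- unpack_entry(map$entries, map$region)
  ok <- !is.na(dec$x)
  expect_true(all(dec$x[ok] >= map$region[1] & dec$x[ok] <= map$region[2]))
  expect_true(all(dec$y[ok] >= map$region[3] & dec$y[ok] <= map$region[4]))
})

test_that("decoded intersections reproduce their level pairs", {
  m <- default_model()
  map <- default_map()
  dec <- unpack_entry(map$entries, map$region)
  ok <- which(!is.na(dec$x))
  h_idx <- (ok - 1) %/% map$v_levels$n_levels + 1
  v_idx <- (ok - 1) %% map$v_levels$n_levels + 1
  h_err <- abs(m$h_field(dec$x[ok], dec$y[ok]) - map$h_levels$levels[h_idx])
  v_err <- abs(m$v_field(dec$x[ok], dec$y[ok]) - map$v_levels$levels[v_idx])
  expect_gte(mean(h_err < map$h_levels$spacing / 2), 0.99)
  expect_gte(mean(v_err < map$v_levels$spacing / 2), 0.99)
})
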