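# Shared fixtures, memoized so the expensive default map is built once per
# test run.

.fixtures <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- qapd_response_model()
  .fixtures$model
}

# The standard 100 nm x 100 nm, 200-level map over the default response.
default_map <- function() {
  if (is.null(.fixtures$map)) {
    pair <- scan_image_pair(default_model())
    .fixtures$map <- build_map(pair, 200)
  }
  .fixtures$map
}

# A synthetic scan pair with perfectly linear orthogonal fields
# (h = x / half, v = y / half): closed-form contours and intersections.
linear_scan_pair <- function(half = 50, pitch = 0.5) {
  xs <- seq(-half, half, by = pitch)
  n <- length(xs)
  h <- matrix(rep(xs / half, each = n), nrow = n)
  v <- matrix(rep(xs / half, times = n), nrow = n)
  structure(list(h_image = h, v_image = v,
                 region = c(-half, half, -half, half),
                 pixel_pitch = pitch, xs = xs, ys = xs),
            class = "scan_image_pair")
}

# Hand-built small contour map from an explicit position grid (h slow axis).
toy_map <- function(grid_x, grid_y, region, holes = integer(0)) {
  nh <- length(grid_x); nv <- length(grid_y)
  pos <- cbind(rep(grid_x, each = nv), rep(grid_y, times = nh))
  entries <- pack_entry(pos, region)
  entries[holes] <- PLACEHOLDER
  lv <- function(n) structure(
    list(levels = seq(-1, 1, length.out = n), n_levels = n,
         spacing = 2 / (n - 1)), class = "contour_levels")
  structure(list(entries = entries, h_levels = lv(nh), v_levels = lv(nv),
                 region = region,
                 build_metadata = list(n_levels = nh),
                 cache = new.env(parent = emptyenv())),
            class = "contour_map")
}

# Independent oracle: invert the noiseless response (h, v) -> (x, y) by
# damped Newton iteration with a finite-difference Jacobian.
invert_response <- function(model, h_target, v_target, start = c(0, 0),
                            tol = 1e-10, max_iter = 60) {
  p <- start
  for (i in seq_len(max_iter)) {
    f <- c(model$h_field(p[1], p[2]) - h_target,
           model$v_field(p[1], p[2]) - v_target)
    if (max(abs(f)) < tol) break
    J <- response_jacobian(model, p)
    step <- solve(J, f)
    # damp long steps to stay in the monotone region
    if (max(abs(step)) > 20) step <- step * 20 / max(abs(step))
    p <- p - step
  }
  p
}

response_jacobian <- function(model, p, eps = 1e-4) {
  matrix(c(
    (model$h_field(p[1] + eps, p[2]) - model$h_field(p[1] - eps, p[2])),
    (model$h_field(p[1], p[2] + eps) - model$h_field(p[1], p[2] - eps)),
    (model$v_field(p[1] + eps, p[2]) - model$v_field(p[1] - eps, p[2])),
    (model$v_field(p[1], p[2] + eps) - model$v_field(p[1], p[2] - eps))),
    2, 2, byrow = TRUE) / (2 * eps)
}

# Per-axis worst-case lookup error bound at a point: half a level spacing in
# each signal channel mapped through the inverse Jacobian, plus pack
# quantization.
lookup_error_bound <- function(model, map, p) {
  Jinv <- solve(response_jacobian(model, p))
  dh <- map$h_levels$spacing / 2
  dv <- map$v_levels$spacing / 2
  packq <- (map$region[2] - map$region[1]) / 65535 / 2
  c(abs(Jinv[1, 1]) * dh + abs(Jinv[1, 2]) * dv + packq,
    abs(Jinv[2, 1]) * dh + abs(Jinv[2, 2]) * dv + packq)
}

# Track a single noiseless sample at position p through the map.
lookup_at <- function(model, map, p) {
  r <- evaluate_response(model, p)
  idx <- signal_to_index(r, map)
  pos <- lookup_position(as.numeric(idx), map)
  c(pos$x, pos$y)
}
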