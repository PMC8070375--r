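# Independent oracles and fixture builders.  Oracles are deliberately
# written as scalar/loop code, separate from the vectorized library paths
# they check.

# Direct scalar evaluation of the polar-grid -> Cartesian transform.
oracle_polar_point <- function(a, r, fov, H, W) {
  dtheta <- fov$theta_c / (W - 1)
  dr <- fov$d_c / (H - 1)
  phi <- -fov$theta_c / 2 + a * dtheta
  rho <- fov$r_c + r * dr
  c(x = rho * sin(phi) + fov$x_offset,
    y = rho * cos(phi) + fov$y_offset)
}

# Point-in-sector membership by cross products against the boundary
# direction vectors (no arctangent).
oracle_in_sector <- function(x, y, fov) {
  vx <- x - fov$x_offset
  vy <- y - fov$y_offset
  rho2 <- vx^2 + vy^2
  if (rho2 < fov$r_c^2 || rho2 > (fov$r_c + fov$d_c)^2) return(FALSE)
  half <- fov$theta_c / 2
  b1 <- c(sin(-half), cos(-half))   # left boundary direction
  b2 <- c(sin(half), cos(half))     # right boundary direction
  # y grows downwards, so the in-screen cross-product signs flip relative
  # to the usual orientation: v between b1 and b2 has b1 x v <= 0 <= b2 x v
  cross1 <- b1[1] * vy - b1[2] * vx
  cross2 <- b2[1] * vy - b2[2] * vx
  cross1 <= 0 && cross2 >= 0
}

# Per-point loop bilinear sampler; same stencil expression as the library
# so agreement must be bit-for-float.
oracle_bilinear <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (!is.finite(x[i]) || !is.finite(y[i]) ||
        x[i] < 0 || x[i] > nc - 1 || y[i] < 0 || y[i] > nr - 1) {
      out[i] <- fill
      next
    }
    x0 <- min(floor(x[i]), nc - 1); y0 <- min(floor(y[i]), nr - 1)
    fx <- x[i] - floor(x[i]); fy <- y[i] - floor(y[i])
    x1 <- min(x0 + 1, nc - 1); y1 <- min(y0 + 1, nr - 1)
    out[i] <- (1 - fx) * (1 - fy) * img[y0 + 1, x0 + 1] +
      fx * (1 - fy) * img[y0 + 1, x1 + 1] +
      (1 - fx) * fy * img[y1 + 1, x0 + 1] +
      fx * fy * img[y1 + 1, x1 + 1]
  }
  out
}

# Loop reimplementation of the pixel-centre-aligned downsampler.
oracle_downsample <- function(img, h, w) {
  out <- matrix(0, h, w)
  sy <- nrow(img) / h; sx <- ncol(img) / w
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      y <- min(max((i - 0.5) * sy - 0.5, 0), nrow(img) - 1)
      x <- min(max((j - 0.5) * sx - 0.5, 0), ncol(img) - 1)
      out[i, j] <- oracle_bilinear(img, x, y)
    }
  }
  out
}

# Minimum number of contiguous segments covering `layers` such that each
# segment sums to <= budget, except that a single over-budget layer may
# stand alone.  Exhaustive recursion (use only for short lists).
oracle_min_segments <- function(layers, budget) {
  n <- length(layers)
  if (n == 0) return(0L)
  best <- Inf
  for (len in seq_len(n)) {
    s <- sum(layers[seq_len(len)])
    if (s > budget && len > 1) break
    best <- min(best, 1L + oracle_min_segments(layers[-seq_len(len)], budget))
    if (s > budget) break   # singleton overrun: longer prefixes invalid
  }
  best
}

# Geometry that fits a (rows, cols) canvas with the requested parameters.
fitted_fov <- function(r_c, theta_deg, canvas = c(500L, 600L),
                       dx = 0, top = 15, depth_frac = 0.9) {
  theta <- theta_deg * pi / 180
  y0 <- top - r_c * cos(theta / 2)
  d_max <- min(canvas[[1]] - 15 - y0,
               (canvas[[2]] / 2 - 15 - abs(dx)) / sin(theta / 2)) - r_c
  fov_geometry(canvas[[2]] / 2 + dx, y0, r_c, theta, depth_frac * d_max,
               kind = if (r_c == 0) "sector" else "convex")
}

# Render a bland phantom frame with known geometry.
render_phantom_frame <- function(fov, canvas = c(500L, 600L),
                                 speckle = FALSE, seed = 1L,
                                 grid_shape = c(160L, 128L),
                                 background = 150) {
  spec <- phantom_spec(grid_shape, background = background,
                       speckle = speckle, seed = seed)
  render_display_frame(generate_echo_phantom(spec, fov), canvas = canvas)
}

# A smooth (speckle-free) phantom with two inclusions, for resampling
# fidelity checks.
smooth_structured_echo <- function(fov, grid_shape = c(200L, 160L)) {
  H <- grid_shape[[1]]; W <- grid_shape[[2]]
  spec <- phantom_spec(
    grid_shape, background = 140, speckle = FALSE,
    inclusions = list(
      phantom_inclusion(c(0.5 * H, 0.38 * W), c(0.15 * H, 0.13 * W),
                        "hypoechoic"),
      phantom_inclusion(c(0.3 * H, 0.68 * W), c(0.1 * H, 0.11 * W),
                        "hyperechoic")),
    seed = 1L)
  generate_echo_phantom(spec, fov)
}

expect_fov_close <- function(est, truth, tol_deg = 1, tol_px = 2) {
  expect_false(est$kind == "linear")
  expect_lt(abs(est$theta_c - truth$theta_c) * 180 / pi, tol_deg)
  expect_lt(abs(est$r_c - truth$r_c), tol_px)
  expect_lt(abs(est$d_c - truth$d_c), tol_px)
  expect_lt(abs(est$x_offset - truth$x_offset), tol_px)
  expect_lt(abs(est$y_offset - truth$y_offset), tol_px)
}

fov_recovered <- function(est, truth, tol_deg = 1, tol_px = 2) {
  !is.null(est) && est$kind != "linear" &&
    abs(est$theta_c - truth$theta_c) * 180 / pi < tol_deg &&
    abs(est$r_c - truth$r_c) < tol_px &&
    abs(est$d_c - truth$d_c) < tol_px &&
    abs(est$x_offset - truth$x_offset) < tol_px &&
    abs(est$y_offset - truth$y_offset) < tol_px
}
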