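test_that("bilinear_sample matches the loop oracle bit-for-float", {
  set.seed(31)
  for (i in 1:20) {
    img <- matrix(runif(40 * 50, 0, 255), 40, 50)
    x <- runif(200, -5, 54); y <- runif(200, -5, 44)
    expect_identical(bilinear_sample(img, x, y), oracle_bilinear(img, x, y))
  }
})

test_that("bilinear outputs are convex combinations of the stencil", {
  set.seed(32)
  for (i in 1:100) {
    img <- matrix(runif(15 * 17, -3, 260), 15, 17)
    x <- runif(100, 0, 16); y <- runif(100, 0, 14)
    v <- bilinear_sample(img, x, y)
    expect_true(all(v >= min(img) - 1e-12))
    expect_true(all(v <= max(img) + 1e-12))
  }
})

test_that("downsampling matches the per-pixel oracle and keeps range", {
  cst <- downsample_image(matrix(42, 30, 40), c(10, 8))
  expect_equal(dim(cst), c(10L, 8L))
  expect_true(all(cst == 42))

  ramp <- matrix(rep(0:127, each = 128), 128, 128)
  got <- downsample_image(ramp, c(64, 64))
  expect_identical(got, oracle_downsample(ramp, 64, 64))
  # rows of a horizontal ramp reproduce the ramp at source positions
  src <- (seq_len(64) - 0.5) * 2 - 0.5
  expect_equal(got[1, ], src, tolerance = 1e-12)

  set.seed(33)
  for (i in 1:20) {
    img <- matrix(runif(48 * 36, 0, 255), 48, 36)
    out <- downsample_image(img, c(17, 13))
    expect_identical(out, oracle_downsample(img, 17, 13))
    expect_gte(min(out), min(img))
    expect_lte(max(out), max(img))
  }
  expect_error(downsample_image(matrix(0, 10, 10), c(20, 5)), "upsample")
})

test_that("reverse scan conversion preserves constants and zeros", {
  fov <- fov_geometry(300, -40, 100, 60 * pi / 180, 330)
  canvas <- c(500L, 600L)
  const <- forward_scan_convert(echo_image(matrix(177, 100, 80), fov),
                                canvas)
  back <- reverse_scan_convert(const, fov, out_shape = c(100, 80))
  # interior grid pixels (2-cell margin keeps stencils off the boundary)
  expect_equal(max(abs(back$data[3:98, 3:78] - 177)), 0, tolerance = 1e-9)

  zeros <- reverse_scan_convert(matrix(0, 500, 600), fov, c(64, 64))
  expect_true(all(zeros$data == 0))
  expect_true(all(is.finite(back$data)))   # every output pixel assigned
})

test_that("forward then reverse conversion is faithful on smooth phantoms", {
  fov <- fov_geometry(400, -61, 120, 65 * pi / 180, 380)
  echo <- smooth_structured_echo(fov)
  disp <- forward_scan_convert(echo, canvas = c(600L, 800L))
  back <- reverse_scan_convert(disp, fov, out_shape = dim(echo$data))
  H <- nrow(echo$data); W <- ncol(echo$data)
  core <- cbind(rep(11:(H - 10), W - 20),
                rep(11:(W - 10), each = H - 20))
  e <- echo$data[core]; b <- back$data[core]
  expect_lt(mean(abs(e - b)), 3)
  ncc <- sum((e - mean(e)) * (b - mean(b))) /
    sqrt(sum((e - mean(e))^2) * sum((b - mean(b))^2))
  expect_gt(ncc, 0.98)
})

test_that("forward conversion paints exactly the analytic sector-annulus", {
  fov <- fov_geometry(300, -61, 120, 65 * pi / 180, 380)
  disp <- forward_scan_convert(echo_image(matrix(200, 150, 120), fov),
                               canvas = c(600L, 600L))
  area <- sum(disp$data > 0)
  analytic <- fov$theta_c / 2 * ((fov$r_c + fov$d_c)^2 - fov$r_c^2)
  expect_lt(abs(area - analytic) / analytic, 0.01)
  # zero echo renders to a black frame
  z <- forward_scan_convert(echo_image(matrix(0, 150, 120), fov),
                            canvas = c(600L, 600L))
  expect_true(all(z$data == 0))
  # FOV entirely off-canvas is signalled
  expect_error(
    forward_scan_convert(echo_image(matrix(1, 10, 10), fov), c(40L, 40L)),
    class = "usrsc_empty_render_error")
})

test_that("an echo impulse lands at its transformed display position", {
  fov <- fov_geometry(300, -50, 110, 58 * pi / 180, 350)
  e <- matrix(0, 180, 140)
  e[91, 51] <- 255                  # (a0, r0) = (50, 90), 0-based
  disp <- forward_scan_convert(echo_image(e, fov), canvas = c(550L, 600L))
  peak <- which(disp$data == max(disp$data), arr.ind = TRUE)[1, ]
  want <- polar_to_cartesian(50, 90, fov, c(180, 140))
  dist <- sqrt((peak[["col"]] - 1 - want$x)^2 +
                 (peak[["row"]] - 1 - want$y)^2)
  expect_lt(dist, 1.5)
})

test_that("pointwise-brighter inputs never darken the resampled output", {
  set.seed(35)
  fov <- fov_geometry(200, -30, 80, 55 * pi / 180, 260)
  e1 <- matrix(runif(90 * 70, 20, 180), 90, 70)
  e2 <- e1 + matrix(runif(90 * 70, 0, 60), 90, 70)
  d1 <- forward_scan_convert(echo_image(e1, fov), c(350L, 400L))
  d2 <- forward_scan_convert(echo_image(e2, fov), c(350L, 400L))
  expect_true(all(d2$data - d1$data >= -1e-12))
  r1 <- reverse_scan_convert(d1, fov, c(90, 70))
  r2 <- reverse_scan_convert(d2, fov, c(90, 70))
  expect_true(all(r2$data - r1$data >= -1e-12))
})

test_that("reverse conversion ignores background pixels of the display", {
  fov <- fov_geometry(250, -40, 90, 60 * pi / 180, 300)
  disp <- forward_scan_convert(
    echo_image(matrix(150, 120, 100), fov), c(450L, 500L))
  xg <- rep(0:499, each = 450); yg <- rep(0:449, times = 500)
  member <- matrix(in_fov(xg, yg, fov), 450, 500)
  altered <- disp$data
  altered[!member] <- 211
  r1 <- reverse_scan_convert(disp$data, fov, c(120, 100))
  r2 <- reverse_scan_convert(altered, fov, c(120, 100))
  # identical except at boundary-straddling stencils: compare the interior
  expect_identical(r1$data[3:118, 3:98], r2$data[3:118, 3:98])
})

test_that("linear geometry takes the crop-and-resize path", {
  lin <- fov_geometry(10, 20, 0, NA, 100, kind = "linear", width = 120)
  frame <- matrix(0, 200, 200)
  frame[21:120, 11:130] <- 99
  expect_error(reverse_scan_convert(frame, lin, c(64, 64)),
               class = "usrsc_linear_fov_error")
  out <- crop_resize_linear(frame, lin, c(64, 64))
  expect_equal(dim(out), c(64L, 64L))
  expect_true(all(out == 99))
})

test_that("images survive PNG write/read with 8-bit quantization", {
  img <- matrix(runif(40 * 30, 0, 255), 40, 30)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  expect_identical(read_image(path), round(img))
  # echo + geometry sidecar round trip
  fov <- fov_geometry(12, -5, 40, pi / 4, 120)
  epath <- withr::local_tempfile(fileext = ".png")
  write_echo_png(echo_image(round(img), fov), epath)
  back <- read_echo_png(epath)
  expect_identical(back$data, round(img))
  expect_equal(back$fov$theta_c, fov$theta_c)
})
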