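test_that("polar_to_cartesian matches closed-form trigonometry", {
  fov <- fov_geometry(0, 0, r_c = 100, theta_c = pi / 3, d_c = 200)
  gs <- c(128L, 128L)
  # central beam, first sample: straight down at radius r_c
  ctr <- polar_to_cartesian((128 - 1) / 2, 0, fov, gs)
  expect_equal(ctr$x, 0, tolerance = 1e-12)
  expect_equal(ctr$y, 100, tolerance = 1e-12)
  # left boundary (phi = -30 deg): sin(-30 deg) = -1/2
  lb <- polar_to_cartesian(0, 0, fov, gs)
  expect_equal(lb$x, -50, tolerance = 1e-9)
  expect_equal(lb$y, 100 * sqrt(3) / 2, tolerance = 1e-9)
})

test_that("transforms agree with an independent scalar oracle", {
  set.seed(101)
  for (i in 1:50) {
    H <- sample(16:256, 1); W <- sample(16:256, 1)
    fov <- fov_geometry(runif(1, -100, 700), runif(1, -200, 100),
                        runif(1, 0, 200), runif(1, 0.2, 2.8),
                        runif(1, 50, 500))
    a <- runif(1, 0, W - 1); r <- runif(1, 0, H - 1)
    got <- polar_to_cartesian(a, r, fov, c(H, W))
    want <- oracle_polar_point(a, r, fov, H, W)
    expect_lt(abs(got$x - want[["x"]]), 1e-9)
    expect_lt(abs(got$y - want[["y"]]), 1e-9)
  }
})

test_that("cartesian_to_polar inverts polar_to_cartesian over the grid", {
  set.seed(7)
  fovs <- replicate(10, fov_geometry(runif(1, 0, 600), runif(1, -150, 50),
                                     runif(1, 0, 180), runif(1, 0.3, 2.6),
                                     runif(1, 80, 400)),
                    simplify = FALSE)
  for (fov in fovs) {
    H <- 200L; W <- 160L
    a <- runif(100, 0, W - 1); r <- runif(100, 0, H - 1)
    xy <- polar_to_cartesian(a, r, fov, c(H, W))
    back <- cartesian_to_polar(xy$x, xy$y, fov, c(H, W))
    expect_lt(max(abs(back$a - a)), 1e-9)
    expect_lt(max(abs(back$r - r)), 1e-9)
  }
})

test_that("grid corners map onto the field-of-view outline", {
  set.seed(11)
  for (i in 1:20) {
    fov <- fov_geometry(runif(1, 0, 500), runif(1, -100, 50),
                        runif(1, 0, 150), runif(1, 0.3, 2.7),
                        runif(1, 60, 400))
    H <- sample(8:300, 1); W <- sample(8:300, 1)
    corners <- list(c(0, 0), c(W - 1, 0), c(0, H - 1), c(W - 1, H - 1))
    for (cr in corners) {
      xy <- polar_to_cartesian(cr[1], cr[2], fov, c(H, W))
      rho <- sqrt((xy$x - fov$x_offset)^2 + (xy$y - fov$y_offset)^2)
      want <- if (cr[2] == 0) fov$r_c else fov$r_c + fov$d_c
      expect_lt(abs(rho - want), 1e-9)
    }
  }
})

test_that("points outside the angular span flag as out-of-grid", {
  fov <- fov_geometry(200, 0, 80, 60 * pi / 180, 250)
  gs <- c(128L, 96L)
  set.seed(3)
  x <- runif(500, -100, 500); y <- runif(500, -50, 450)
  p <- cartesian_to_polar(x, y, fov, gs)
  in_grid <- p$a >= 0 & p$a <= 95 & p$r >= 0 & p$r <= 127
  member <- vapply(seq_along(x),
                   function(i) oracle_in_sector(x[i], y[i], fov), logical(1))
  expect_equal(in_grid, member)
})

test_that("allocate_scanlines spaces angles uniformly across the FOV", {
  fov <- fov_geometry(0, 0, 100, pi / 3, 200)
  two <- allocate_scanlines(fov, 2)
  expect_equal(two$angle, c(-pi / 6, pi / 6))
  three <- allocate_scanlines(fov, 3)
  expect_equal(three$angle, c(-pi / 6, 0, pi / 6))

  fov2 <- fov_geometry(10, -20, 60, 65 * pi / 180, 300)
  sl <- allocate_scanlines(fov2, 128)
  gaps <- diff(sl$angle)
  expect_lt(max(abs(gaps - fov2$theta_c / 127)), 1e-12)
  expect_equal(sl$angle[1], -fov2$theta_c / 2)
  expect_equal(sl$angle[128], fov2$theta_c / 2)
  rho0 <- sqrt((sl$x0 - 10)^2 + (sl$y0 + 20)^2)
  rho1 <- sqrt((sl$x1 - 10)^2 + (sl$y1 + 20)^2)
  expect_lt(max(abs(rho0 - 60)), 1e-9)
  expect_lt(max(abs(rho1 - 360)), 1e-9)
})

test_that("degenerate geometries are rejected with distinct signals", {
  lin <- fov_geometry(0, 0, 0, NA, 100, kind = "linear", width = 200)
  expect_error(polar_to_cartesian(0, 0, lin, c(10, 10)),
               class = "usrsc_linear_fov_error")
  expect_error(cartesian_to_polar(0, 0, lin, c(10, 10)),
               class = "usrsc_linear_fov_error")
  expect_error(allocate_scanlines(lin, 8),
               class = "usrsc_linear_fov_error")
  fov <- fov_geometry(5, 5, 0, pi / 2, 100, kind = "sector")
  expect_warning(p <- cartesian_to_polar(5, 5, fov, c(10, 10)),
                 "apex")
  expect_true(is.nan(p$a))
  expect_error(allocate_scanlines(fov, 1))
  expect_error(fov_geometry(0, 0, -1, pi / 2, 100))
  expect_error(fov_geometry(0, 0, 10, pi / 2, 0))
  expect_error(fov_geometry(0, 0, 10, 3.2, 100))
})

test_that("geometry serializes to flat JSON and back", {
  fov <- fov_geometry(312.25, -41.5, 118, 64.8 * pi / 180, 377.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_fov_json(fov, path)
  back <- read_fov_json(path)
  expect_equal(back[c("x_offset", "y_offset", "r_c", "theta_c", "d_c",
                      "kind")],
               fov[c("x_offset", "y_offset", "r_c", "theta_c", "d_c",
                     "kind")])
  rec <- jsonlite::read_json(path)
  expect_named(rec, c("x_offset", "y_offset", "r_c", "theta_c_deg", "d_c",
                      "kind"))
})
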