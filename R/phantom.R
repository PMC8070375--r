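#' Specify a synthetic echo phantom
#'
#' Describes a speckle phantom on the polar acquisition grid: a background
#' tissue level plus elliptical inclusions with caricatured echogenicity
#' modes (`anechoic` like a fluid-filled gallbladder, `hypoechoic` like
#' renal parenchyma, `hyperechoic` like a bright interface).  Inclusions
#' are painted in order: where they overlap, the last one wins.
#'
#' @param grid_shape Integer `(H, W)`: radial samples x scanlines.
#' @param background Background mean intensity (0-255).
#' @param speckle Logical; draw Rayleigh speckle (TRUE) or emit exact
#'   region means (FALSE, the smooth variant used for resampling-fidelity
#'   checks).
#' @param inclusions List of [phantom_inclusion()] entries, all inside the
#'   grid.
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160L, 128L), background = 128,
                         speckle = TRUE, inclusions = list(), seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 2),
            background >= 0, background <= 255)
  H <- as.integer(grid_shape[[1]]); W <- as.integer(grid_shape[[2]])
  for (inc in inclusions) {
    stopifnot(inherits(inc, "phantom_inclusion"))
    if (inc$center[1] - inc$axes[1] < 0 || inc$center[1] + inc$axes[1] > H - 1 ||
        inc$center[2] - inc$axes[2] < 0 || inc$center[2] + inc$axes[2] > W - 1)
      stop("inclusion extends outside the grid")
  }
  structure(list(grid_shape = c(H, W), background = background,
                 speckle = isTRUE(speckle), inclusions = inclusions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param center `(r, a)` grid position of the ellipse centre (row = radial
#'   sample, col = scanline index).
#' @param axes `(r, a)` semi-axes in grid units.
#' @param mode Echogenicity: `"anechoic"`, `"hypoechoic"` or
#'   `"hyperechoic"`.
#' @param mean Mean intensity; defaults per mode (4, 60, 230).
#' @export
phantom_inclusion <- function(center, axes,
                              mode = c("anechoic", "hypoechoic",
                                       "hyperechoic"),
                              mean = NULL) {
  mode <- match.arg(mode)
  if (is.null(mean))
    mean <- c(anechoic = 4, hypoechoic = 60, hyperechoic = 230)[[mode]]
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0),
            mean >= 0, mean <= 255)
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 mode = mode, mean = as.numeric(mean)),
            class = "phantom_inclusion")
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# E[log1p(gamma * E)] for a Rayleigh envelope E with unit mean, by numeric
# quadrature; calibrates the log-compressed speckle to hit a target mean.
log_compression_norm <- function(gamma) {
  sigma <- sqrt(2 / pi)
  stats::integrate(function(e) {
    log1p(gamma * e) * (e / sigma^2) * exp(-e^2 / (2 * sigma^2))
  }, 0, Inf, rel.tol = 1e-10)$value
}

#' Generate a synthetic echo phantom
#'
#' Realizes a [phantom_spec()] on the polar grid.  With speckle enabled,
#' each pixel draws a Rayleigh-distributed envelope (unit mean), which is
#' log-compressed (`log1p(gamma * E)`) and scaled so the compressed field's
#' expected value equals the region's target mean — so anechoic regions stay
#' near 0, hyperechoic ones near saturation, and the background speckle
#' averages to its nominal level.  Intensities are clipped to [0, 255].
#' With speckle disabled the exact region means are emitted.
#'
#' @param spec A [phantom_spec()].
#' @param fov The [fov_geometry()] to attach to the echo image; default a
#'   centred convex probe on an 800 x 600 display ([default_fov()]).
#' @param gamma Log-compression strength (dimensionless, > 0).
#' @return An [echo_image()].
#' @export
generate_echo_phantom <- function(spec, fov = default_fov(), gamma = 10) {
  stopifnot(inherits(spec, "phantom_spec"), gamma > 0)
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  means <- matrix(spec$background, H, W)
  rr <- matrix(0:(H - 1), H, W)
  aa <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (inc in spec$inclusions) {
    inside <- ((rr - inc$center[1]) / inc$axes[1])^2 +
      ((aa - inc$center[2]) / inc$axes[2])^2 <= 1
    means[inside] <- inc$mean
  }
  if (!spec$speckle) return(echo_image(means, fov))
  img <- with_local_seed(spec$seed, {
    sigma <- sqrt(2 / pi)
    env <- sigma * sqrt(-2 * log(stats::runif(H * W)))
    compressed <- log1p(gamma * env) / log_compression_norm(gamma)
    means * matrix(compressed, H, W)
  })
  echo_image(pmin(pmax(img, 0), 255), fov)
}

#' Default convex-probe geometry centred on a display canvas
#'
#' A convex abdominal-style FOV (65 degree opening, 120 px transducer
#' radius, 380 px depth) centred laterally on the canvas with a 40 px top
#' margin.  Used as the stock geometry for phantoms and examples.
#'
#' @param canvas Integer `(rows, cols)` display size; default 600 x 800,
#'   a common display-frame resolution.
#' @return A [fov_geometry()].
#' @export
default_fov <- function(canvas = c(600L, 800L)) {
  theta_c <- 65 * pi / 180
  r_c <- 120; top_margin <- 40
  scale <- min(1, canvas[[1]] / 600)
  r_c <- r_c * scale
  d_c <- 380 * scale
  fov_geometry(x_offset = (canvas[[2]] - 1) / 2,
               y_offset = top_margin - r_c * cos(theta_c / 2),
               r_c = r_c, theta_c = theta_c, d_c = d_c, kind = "convex")
}

#' Render an echo phantom to a display frame
#'
#' Scan-converts the echo grid onto a black canvas via
#' [forward_scan_convert()] and returns both the frame and the exact
#' geometry used — the ground truth against which geometry estimation is
#' validated.
#'
#' @param echo An [echo_image()].
#' @param canvas Integer `(rows, cols)`.
#' @param apex Optional apex placement override (`(x, y)`).
#' @return A list with `frame` (a [display_image()]) and `fov` (the
#'   effective [fov_geometry()]).
#' @export
render_display_frame <- function(echo, canvas = c(600L, 800L), apex = NULL) {
  frame <- forward_scan_convert(echo, canvas = canvas, apex = apex)
  list(frame = frame, fov = frame$fov)
}

#' Draw a random in-canvas field-of-view geometry
#'
#' Samples a convex or sector geometry that fits the canvas with a margin:
#' opening angle uniform on [35, 90] degrees, transducer radius uniform on
#' [0, 150] px (snapped to 0 with probability 0.2 to exercise the sector
#' case), lateral apex jitter, and depth filling 70-100% of the available
#' room.  Uses the current RNG stream.
#'
#' @param canvas Integer `(rows, cols)`.
#' @param margin Minimum distance (px) from the FOV to the canvas edge.
#' @return A [fov_geometry()].
#' @export
random_fov <- function(canvas = c(500L, 600L), margin = 12) {
  rows <- canvas[[1]]; cols <- canvas[[2]]
  for (i in 1:50) {
    theta_c <- stats::runif(1, 35, 90) * pi / 180
    r_c <- if (stats::runif(1) < 0.2) 0 else stats::runif(1, 6, 150)
    dx <- stats::runif(1, -25, 25)
    top <- stats::runif(1, margin, margin + 15)
    y_offset <- top - r_c * cos(theta_c / 2)
    max_reach <- min(rows - margin - y_offset,
                     (cols / 2 - margin - abs(dx)) / sin(theta_c / 2))
    d_max <- max_reach - r_c
    if (d_max < 80) next
    d_c <- stats::runif(1, 0.7, 1) * d_max
    return(fov_geometry(cols / 2 + dx, y_offset, r_c, theta_c, d_c,
                        kind = if (r_c == 0) "sector" else "convex"))
  }
  stop("could not place a random FOV on the canvas")
}

#' Generate a labeled phantom dataset of display frames
#'
#' Writes `n_per_class` rendered frames per class to `out_dir` as 8-bit
#' grayscale PNGs, with class-specific inclusion recipes: `liver` is uniform
#' speckle, `kidney` a hypoechoic ellipse with a hyperechoic rim,
#' `gallbladder` a large anechoic ellipse.  Geometry varies per frame
#' ([random_fov()]).  The recipes are caricatures that exercise the
#' preprocessing pipeline, not anatomical models.
#'
#' @param n_per_class Frames per class, >= 1.
#' @param classes Character vector of class labels (recognized recipes:
#'   liver, kidney, gallbladder; unknown labels fall back to plain speckle).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @param canvas Display canvas `(rows, cols)` per frame.
#' @param grid_shape Echo grid `(H, W)` per frame.
#' @return A manifest data.frame with columns `file`, `label`, and the
#'   ground-truth geometry (`kind`, `x_offset`, `y_offset`, `r_c`,
#'   `theta_c_deg`, `d_c`); also written to `manifest.csv` in `out_dir`.
#' @export
generate_labeled_dataset <- function(n_per_class, classes = c("liver",
                                       "kidney", "gallbladder"),
                                     out_dir, seed = 1L,
                                     canvas = c(500L, 600L),
                                     grid_shape = c(160L, 128L)) {
  stopifnot(n_per_class >= 1, length(classes) >= 1)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- with_local_seed(seed, {
    recs <- list()
    k <- 0L
    for (cls in classes) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        fov <- random_fov(canvas)
        spec <- class_phantom_spec(cls, grid_shape,
                                   seed = sample.int(2^30, 1))
        echo <- generate_echo_phantom(spec, fov)
        fr <- render_display_frame(echo, canvas = canvas)
        file <- file.path(out_dir, sprintf("%s_%03d.png", cls, i))
        write_image_png(fr$frame, file)
        recs[[k]] <- data.frame(
          file = file, label = cls, kind = fov$kind,
          x_offset = fov$x_offset, y_offset = fov$y_offset, r_c = fov$r_c,
          theta_c_deg = fov$theta_c * 180 / pi, d_c = fov$d_c,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  })
  utils::write.csv(rows, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  rows
}

# Class-specific inclusion recipes on grid (H, W).
class_phantom_spec <- function(label, grid_shape, seed) {
  H <- grid_shape[1]; W <- grid_shape[2]
  cr <- c(stats::runif(1, 0.35, 0.65) * (H - 1),
          stats::runif(1, 0.35, 0.65) * (W - 1))
  inclusions <- switch(
    label,
    liver = list(),
    kidney = {
      ax <- c(stats::runif(1, 0.12, 0.18) * H, stats::runif(1, 0.12, 0.18) * W)
      list(phantom_inclusion(cr, ax * 1.35, mode = "hyperechoic"),
           phantom_inclusion(cr, ax, mode = "hypoechoic"))
    },
    gallbladder = {
      ax <- c(stats::runif(1, 0.16, 0.24) * H, stats::runif(1, 0.16, 0.24) * W)
      list(phantom_inclusion(cr, ax, mode = "anechoic"))
    },
    list())
  phantom_spec(grid_shape, background = 120, speckle = TRUE,
               inclusions = inclusions, seed = seed)
}
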