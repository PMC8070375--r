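#' Field-of-view geometry of a convex or sector probe
#'
#' Parameterizes the field of view (FOV) that a convex or sector array
#' transducer paints on the display raster: an annular sector centred on a
#' (virtual) apex.  All lengths are in display pixels, all angles in radians.
#' Coordinates are 0-based and pixel-centred: image pixel (row k, col l) sits
#' at Cartesian position (x = l, y = k), with y increasing downwards so the
#' beam axis points along +y.
#'
#' @param x_offset,y_offset Apex position in display pixel coordinates
#'   (continuous; the apex may lie outside the visible frame).
#' @param r_c Transducer radius: distance from the apex to the top of the
#'   FOV, in pixels.  Must be >= 0; a sector (phased-array) FOV has
#'   `r_c` at or near 0.
#' @param theta_c Total FOV opening angle in radians, in (0, pi).  Ignored
#'   (and stored as `NA`) for `kind = "linear"`.
#' @param d_c Imaging depth: radial extent of the FOV beyond `r_c`, in
#'   pixels.  Must be > 0.
#' @param kind One of `"convex"`, `"sector"`, `"linear"`.  `"linear"` is the
#'   degenerate parallel-scanline case (rectangular FOV) for which the polar
#'   parameterization does not apply.
#' @param width Lateral extent in pixels, only meaningful (and only stored)
#'   for `kind = "linear"`, whose FOV is the rectangle of size
#'   `d_c` x `width` with top-left corner at the offsets.
#'
#' @return An object of class `fov_geometry`.
#' @examples
#' fov <- fov_geometry(x_offset = 300, y_offset = -40, r_c = 120,
#'                     theta_c = 65 * pi / 180, d_c = 380)
#' fov
#' @export
fov_geometry <- function(x_offset, y_offset, r_c, theta_c, d_c,
                         kind = c("convex", "sector", "linear"),
                         width = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x_offset), is.numeric(y_offset),
            length(x_offset) == 1L, length(y_offset) == 1L,
            is.finite(x_offset), is.finite(y_offset))
  if (!is.numeric(r_c) || length(r_c) != 1L || !is.finite(r_c) || r_c < 0)
    stop("`r_c` must be a single finite number >= 0")
  if (!is.numeric(d_c) || length(d_c) != 1L || !is.finite(d_c) || d_c <= 0)
    stop("`d_c` must be a single finite number > 0")
  if (kind %in% c("convex", "sector")) {
    if (!is.numeric(theta_c) || length(theta_c) != 1L || !is.finite(theta_c) ||
        theta_c <= 0 || theta_c >= pi)
      stop("`theta_c` must be in (0, pi) for convex/sector geometry")
  } else {
    theta_c <- NA_real_
  }
  if (kind != "linear") width <- NA_real_
  structure(
    list(x_offset = as.numeric(x_offset), y_offset = as.numeric(y_offset),
         r_c = as.numeric(r_c), theta_c = as.numeric(theta_c),
         d_c = as.numeric(d_c), kind = kind, width = as.numeric(width)),
    class = "fov_geometry")
}

#' @export
print.fov_geometry <- function(x, ...) {
  cat("<fov_geometry>", x$kind, "\n")
  cat(sprintf("  apex     : (%.2f, %.2f) px\n", x$x_offset, x$y_offset))
  cat(sprintf("  r_c      : %.2f px\n", x$r_c))
  if (is.finite(x$theta_c))
    cat(sprintf("  theta_c  : %.3f rad (%.2f deg)\n",
                x$theta_c, x$theta_c * 180 / pi))
  cat(sprintf("  d_c      : %.2f px\n", x$d_c))
  invisible(x)
}

stop_linear_fov <- function(what) {
  stop(errorCondition(
    paste0(what, " requires a convex or sector geometry, not `linear`"),
    class = c("usrsc_linear_fov_error", "usrsc_error")))
}

# Per-grid angular/radial sample spacing.  A grid of W scanlines spans the
# full opening angle inclusively (scanline 1 on the left boundary, scanline W
# on the right), so spacing uses W - 1 intervals; likewise H radial samples
# span [r_c, r_c + d_c].
grid_spacing <- function(fov, grid_shape) {
  H <- grid_shape[[1]]; W <- grid_shape[[2]]
  if (H < 2 || W < 2) stop("grid_shape must be at least (2, 2)")
  list(dr = fov$d_c / (H - 1), dtheta = fov$theta_c / (W - 1))
}

#' Polar grid index to Cartesian display position
#'
#' Maps continuous acquisition-grid indices `(a, r)` — `a` the scanline
#' (angular) index in `[0, W-1]`, `r` the radial sample index in `[0, H-1]` —
#' to the Cartesian display position of that echo sample.  The beam at
#' angular index `a` makes angle `phi = -theta_c/2 + a * dtheta` with the
#' downward display axis (`dtheta = theta_c / (W - 1)`), and the sample sits
#' at radius `rho = r_c + r * dr` from the apex (`dr = d_c / (H - 1)`):
#' `x = rho * sin(phi) + x_offset`, `y = rho * cos(phi) + y_offset`.
#'
#' Vectorized over `a` and `r`.
#'
#' @param a,r Continuous grid indices (angular, radial); sub-sample positions
#'   are allowed and values outside the grid extrapolate along the same
#'   parameterization.
#' @param fov A [fov_geometry()]; must be convex or sector.
#' @param grid_shape Integer `(H, W)`: number of radial samples and number of
#'   scanlines of the grid the indices refer to.
#' @return A list with numeric vectors `x` and `y`.
#' @seealso [cartesian_to_polar()] for the inverse.
#' @examples
#' fov <- fov_geometry(0, 0, r_c = 100, theta_c = pi / 3, d_c = 200)
#' polar_to_cartesian(a = 0, r = 0, fov, grid_shape = c(128, 96))
#' @export
polar_to_cartesian <- function(a, r, fov, grid_shape) {
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("polar_to_cartesian")
  sp <- grid_spacing(fov, grid_shape)
  phi <- -fov$theta_c / 2 + a * sp$dtheta
  rho <- fov$r_c + r * sp$dr
  list(x = rho * sin(phi) + fov$x_offset,
       y = rho * cos(phi) + fov$y_offset)
}

#' Cartesian display position to polar grid index
#'
#' Inverse of [polar_to_cartesian()]: recovers continuous grid indices
#' `a = (atan2(x - x_offset, y - y_offset) + theta_c/2) / dtheta` and
#' `r = (sqrt((x - x_offset)^2 + (y - y_offset)^2) - r_c) / dr`.  Points
#' outside the FOV map to out-of-grid indices (`a < 0`, `a > W - 1`, `r < 0`
#' or `r > H - 1`); callers filter.  A point exactly at the apex of a
#' zero-radius (sector) geometry has no defined beam angle: its `a` is
#' returned as `NaN` with a warning.
#'
#' @inheritParams polar_to_cartesian
#' @param x,y Cartesian display coordinates (continuous pixels), vectorized.
#' @return A list with numeric vectors `a` and `r`.
#' @export
cartesian_to_polar <- function(x, y, fov, grid_shape) {
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("cartesian_to_polar")
  sp <- grid_spacing(fov, grid_shape)
  dx <- x - fov$x_offset
  dy <- y - fov$y_offset
  rho <- sqrt(dx * dx + dy * dy)
  phi <- atan2(dx, dy)                      # angle from the downward axis
  at_apex <- rho == 0
  if (any(at_apex)) {
    phi[at_apex] <- NaN
    warning("point(s) at the apex: beam angle undefined, `a` set to NaN")
  }
  list(a = (phi + fov$theta_c / 2) / sp$dtheta,
       r = (rho - fov$r_c) / sp$dr)
}

#' Allocate N scanlines uniformly over the field of view
#'
#' Distributes `N` beam directions with uniform angular spacing over the full
#' opening angle: the first scanline lies on the left FOV boundary
#' (`-theta_c/2`), the last on the right (`+theta_c/2`).  Each scanline runs
#' from radius `r_c` (origin) to `r_c + d_c` (endpoint) from the apex.
#'
#' @inheritParams polar_to_cartesian
#' @param n Number of scanlines, >= 2.
#' @return A data.frame with one row per scanline: `angle` (radians from the
#'   downward axis), `x0`, `y0` (origin), `x1`, `y1` (endpoint).
#' @export
allocate_scanlines <- function(fov, n) {
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("allocate_scanlines")
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2")
  angle <- seq(-fov$theta_c / 2, fov$theta_c / 2, length.out = n)
  data.frame(
    angle = angle,
    x0 = fov$r_c * sin(angle) + fov$x_offset,
    y0 = fov$r_c * cos(angle) + fov$y_offset,
    x1 = (fov$r_c + fov$d_c) * sin(angle) + fov$x_offset,
    y1 = (fov$r_c + fov$d_c) * cos(angle) + fov$y_offset)
}

#' Test Cartesian points for membership in the field of view
#'
#' A point belongs to the FOV when its apex distance lies in
#' `[r_c, r_c + d_c]` and its beam angle within `[-theta_c/2, +theta_c/2]`.
#'
#' @inheritParams cartesian_to_polar
#' @return Logical vector.
#' @export
in_fov <- function(x, y, fov) {
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("in_fov")
  dx <- x - fov$x_offset
  dy <- y - fov$y_offset
  rho <- sqrt(dx * dx + dy * dy)
  phi <- atan2(dx, dy)
  rho >= fov$r_c & rho <= fov$r_c + fov$d_c & abs(phi) <= fov$theta_c / 2
}

#' Read and write field-of-view geometry as JSON
#'
#' The on-disk form is a flat mapping with keys `x_offset`, `y_offset`,
#' `r_c`, `theta_c_deg`, `d_c`, `kind`; angles are stored in degrees at this
#' boundary only.
#'
#' @param fov A [fov_geometry()].
#' @param path File path.
#' @return `read_fov_json()` returns a `fov_geometry`; `write_fov_json()`
#'   invisibly returns `path`.
#' @export
write_fov_json <- function(fov, path) {
  stopifnot(inherits(fov, "fov_geometry"))
  rec <- list(x_offset = fov$x_offset, y_offset = fov$y_offset,
              r_c = fov$r_c,
              theta_c_deg = if (is.finite(fov$theta_c))
                fov$theta_c * 180 / pi else NA,
              d_c = fov$d_c, kind = fov$kind)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fov_json
#' @export
read_fov_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- if (is.null(rec$theta_c_deg) || is.na(rec$theta_c_deg))
    NA_real_ else rec$theta_c_deg * pi / 180
  fov_geometry(rec$x_offset, rec$y_offset, rec$r_c, theta, rec$d_c,
               kind = rec$kind)
}
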