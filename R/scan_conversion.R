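#' Echo-memory and display-frame containers
#'
#' `echo_image()` wraps a polar acquisition-grid intensity matrix — rows are
#' radial samples (H), columns are scanlines (W), mirroring the echo-memory
#' layout of a beamformed frame — together with the [fov_geometry()] that
#' places it on the display.  `display_image()` wraps a Cartesian
#' scan-converted raster (rows x cols), optionally with its geometry and the
#' ultrasound-image-region (UIR) crop rectangle.
#'
#' @param data Numeric matrix of intensities (8-bit scale, 0-255, but any
#'   finite values are accepted).
#' @param fov A [fov_geometry()], or NULL for a bare display raster.
#' @param crop A [uir_crop()] or NULL.
#' @return An object of class `echo_image` or `display_image`; both are
#'   lists with a `$data` matrix.
#' @export
echo_image <- function(data, fov) {
  stopifnot(is.matrix(data), all(is.finite(data)), inherits(fov, "fov_geometry"))
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("echo grid must be at least 2 x 2")
  structure(list(data = data, fov = fov), class = "echo_image")
}

#' @rdname echo_image
#' @export
display_image <- function(data, fov = NULL, crop = NULL) {
  stopifnot(is.matrix(data))
  if (!is.null(fov)) stopifnot(inherits(fov, "fov_geometry"))
  structure(list(data = data, fov = fov, crop = crop),
            class = "display_image")
}

#' @export
print.echo_image <- function(x, ...) {
  cat(sprintf("<echo_image> %d radial samples x %d scanlines (%s FOV)\n",
              nrow(x$data), ncol(x$data), x$fov$kind))
  invisible(x)
}

#' @export
print.display_image <- function(x, ...) {
  cat(sprintf("<display_image> %d x %d%s\n", nrow(x$data), ncol(x$data),
              if (is.null(x$fov)) "" else paste0(" (", x$fov$kind, " FOV)")))
  invisible(x)
}

#' @export
as.matrix.echo_image <- function(x, ...) x$data

#' @export
as.matrix.display_image <- function(x, ...) x$data

img_data <- function(img) {
  if (inherits(img, c("echo_image", "display_image"))) img$data
  else if (is.matrix(img)) img
  else stop("expected a matrix, echo_image or display_image")
}

#' Reverse scan conversion: display raster to polar acquisition grid
#'
#' Recovers the pre-scan-conversion (polar-grid) representation of a
#' scan-converted display frame.  The method iterates over the output grid:
#' every polar pixel `(a, r)` is mapped by [polar_to_cartesian()] to its
#' source position on the display and sampled there with bilinear
#' interpolation.  Because the output is traversed directly, every polar
#' pixel receives a value by construction — the inverse-mapping formulation
#' of the resampling, which needs no hole-filling pass (a forward scatter of
#' display pixels onto the polar grid would leave unassigned pixels that
#' must then be interpolated; both formulations evaluate the same bilinear
#' model).  Source positions outside the display bounds yield 0.
#'
#' @param img A [display_image()] or plain matrix.
#' @param fov The [fov_geometry()] describing the FOV in `img`; convex or
#'   sector.  For a `linear` geometry use [crop_resize_linear()], the
#'   rectangular path.
#' @param out_shape Integer `(H, W)`: radial samples x scanlines of the
#'   output grid; both >= 2.
#' @return An [echo_image()] of shape `out_shape` carrying `fov`.
#' @examples
#' fov <- fov_geometry(150, 10, r_c = 40, theta_c = pi / 3, d_c = 180)
#' disp <- matrix(128, 250, 300)
#' rsc <- reverse_scan_convert(disp, fov, out_shape = c(96, 64))
#' @export
reverse_scan_convert <- function(img, fov, out_shape) {
  m <- img_data(img)
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("reverse_scan_convert")
  H <- as.integer(out_shape[[1]]); W <- as.integer(out_shape[[2]])
  if (H < 2 || W < 2) stop("out_shape must be at least (2, 2)")
  a <- rep(0:(W - 1), each = H)
  r <- rep(0:(H - 1), times = W)
  src <- polar_to_cartesian(a, r, fov, grid_shape = c(H, W))
  vals <- bilinear_sample(m, src$x, src$y, fill = 0)
  echo_image(matrix(vals, nrow = H, ncol = W), fov)
}

#' Forward digital scan conversion: polar grid to display raster
#'
#' Renders an echo-memory grid onto a Cartesian canvas: every canvas pixel
#' inside the FOV is mapped by [cartesian_to_polar()] to continuous grid
#' indices and bilinearly sampled from the echo data; pixels outside the FOV
#' are set to 0 (black background).
#'
#' @param echo An [echo_image()], or a plain matrix with `fov` supplied.
#' @param canvas Integer `(rows, cols)` of the output raster.
#' @param apex Optional length-2 numeric `(x, y)` overriding the apex
#'   position of the echo's geometry on this canvas (placement); default
#'   uses the geometry's own offsets.
#' @param fov Geometry when `echo` is a bare matrix.
#' @return A [display_image()] whose `$fov` records the effective geometry
#'   used (ground truth for downstream geometry estimation).
#' @export
forward_scan_convert <- function(echo, canvas, apex = NULL, fov = NULL) {
  if (inherits(echo, "echo_image")) {
    m <- echo$data; fov <- echo$fov
  } else {
    m <- img_data(echo)
    if (is.null(fov)) stop("`fov` is required when `echo` is a bare matrix")
  }
  stopifnot(inherits(fov, "fov_geometry"))
  if (fov$kind == "linear") stop_linear_fov("forward_scan_convert")
  if (!is.null(apex)) {
    fov <- fov_geometry(apex[[1]], apex[[2]], fov$r_c, fov$theta_c, fov$d_c,
                        kind = fov$kind)
  }
  nr <- as.integer(canvas[[1]]); nc <- as.integer(canvas[[2]])
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  member <- in_fov(x, y, fov)
  if (!any(member)) {
    stop(errorCondition(
      "FOV has no visible area on the canvas",
      class = c("usrsc_empty_render_error", "usrsc_error")))
  }
  out <- numeric(nr * nc)
  p <- suppressWarnings(
    cartesian_to_polar(x[member], y[member], fov, grid_shape = dim(m)))
  # a sector apex pixel (radius 0) has no beam angle; render it from the
  # central scanline's first sample
  p$a[!is.finite(p$a)] <- (ncol(m) - 1) / 2
  out[member] <- bilinear_sample(m, p$a, p$r, fill = 0)
  display_image(matrix(out, nrow = nr, ncol = nc), fov = fov)
}

#' Rectangular (linear-array) preprocessing path
#'
#' For a linear-array frame the FOV is already rectangular, so recovering a
#' polar grid does not apply: the path is crop to the FOV rectangle, then
#' bilinear resize.
#'
#' @param img Matrix or [display_image()].
#' @param fov A `linear` [fov_geometry()] (offsets = top-left corner,
#'   `d_c` = height, `width` = width).
#' @param out_shape Output `(h, w)`.
#' @return Numeric matrix of shape `out_shape`.
#' @export
crop_resize_linear <- function(img, fov, out_shape = c(64L, 64L)) {
  m <- img_data(img)
  stopifnot(inherits(fov, "fov_geometry"), fov$kind == "linear")
  r0 <- max(1L, as.integer(round(fov$y_offset)) + 1L)
  c0 <- max(1L, as.integer(round(fov$x_offset)) + 1L)
  r1 <- min(nrow(m), r0 + as.integer(round(fov$d_c)) - 1L)
  wd <- if (is.finite(fov$width)) as.integer(round(fov$width)) else ncol(m)
  c1 <- min(ncol(m), c0 + wd - 1L)
  downsample_image(m[r0:r1, c0:c1, drop = FALSE], out_shape)
}
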