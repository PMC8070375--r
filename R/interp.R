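#' Bilinear sampling of an image at continuous positions
#'
#' Samples `img` at continuous pixel-centre coordinates `(x, y)` (0-based:
#' `x` along columns, `y` along rows) with bilinear interpolation.  The
#' 2 x 2 stencil is clamped at the image border, so positions inside the
#' image but within half a pixel of the edge interpolate from edge pixels.
#' Positions strictly outside `[0, ncol-1] x [0, nrow-1]` return `fill`
#' (default 0, the black background of a display frame) — no extrapolation.
#'
#' @param img Numeric matrix (rows x cols).
#' @param x,y Numeric vectors of equal length; sampling positions.
#' @param fill Value returned for out-of-bounds positions.
#' @return Numeric vector of sampled values, same length as `x`.
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  stopifnot(is.matrix(img), length(x) == length(y))
  nr <- nrow(img); nc <- ncol(img)
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1 &
    is.finite(x) & is.finite(y)
  out <- rep(as.numeric(fill), length(x))
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0;   fy <- yi - y0
  # clamp the stencil: at the far edge floor() == last index, x1 == x0
  x0 <- pmin(x0, nc - 1); y0 <- pmin(y0, nr - 1)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  i00 <- y0 + 1 + x0 * nr; i01 <- y0 + 1 + x1 * nr
  i10 <- y1 + 1 + x0 * nr; i11 <- y1 + 1 + x1 * nr
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i01] +
    (1 - fx) * fy * img[i10] + fx * fy * img[i11]
  out[inside] <- v
  out
}

#' Downsample an image by bilinear resampling
#'
#' Resamples `img` to `out_shape` with plain bilinear interpolation (no
#' anti-aliasing prefilter).  Output pixel `(i, j)` (0-based) samples the
#' source at the pixel-centre-aligned position
#' `x = (j + 0.5) * ncol/w - 0.5`, `y = (i + 0.5) * nrow/h - 0.5`.
#' Intensities stay within the input range because bilinear weights form a
#' convex combination.  Upsampling is rejected: this routine is the
#' reduction step of the preprocessing path (display frame or polar image
#' down to a small network input, 64 x 64 by default).
#'
#' @param img Numeric matrix.
#' @param out_shape Integer `(h, w)`, each at most the corresponding input
#'   dimension.
#' @return Numeric `h x w` matrix.
#' @export
downsample_image <- function(img, out_shape = c(64L, 64L)) {
  stopifnot(is.matrix(img), length(out_shape) == 2L)
  h <- as.integer(out_shape[[1]]); w <- as.integer(out_shape[[2]])
  if (h < 1 || w < 1) stop("out_shape must be positive")
  if (h > nrow(img) || w > ncol(img))
    stop("downsample_image() does not upsample: out_shape exceeds input shape")
  sy <- nrow(img) / h; sx <- ncol(img) / w
  ys <- (seq_len(h) - 0.5) * sy - 0.5
  xs <- (seq_len(w) - 0.5) * sx - 0.5
  # clamp pixel-centre positions at the border (stencil clamp equivalent)
  ys <- pmin(pmax(ys, 0), nrow(img) - 1)
  xs <- pmin(pmax(xs, 0), ncol(img) - 1)
  xg <- rep(xs, each = h)
  yg <- rep(ys, times = w)
  matrix(bilinear_sample(img, xg, yg), nrow = h, ncol = w)
}
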