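#' Read and write 8-bit grayscale images
#'
#' Frames are held in-memory as numeric matrices on the 0-255 scale.
#' `read_image()` accepts PNG (any channel count; multi-channel input is
#' averaged to grayscale) and plain-text PGM (`P2`).  `write_image_png()`
#' quantizes to 8 bits (rounding, clipping to [0, 255]) before writing, so a
#' written-then-read image equals `round(pmin(pmax(x, 0), 255))`.
#'
#' @param path File path (`.png` or `.pgm`).
#' @param img Numeric matrix, or a [display_image()] / [echo_image()].
#' @return `read_image()` returns a numeric matrix (0-255);
#'   `write_image_png()` invisibly returns `path`.
#' @export
read_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  round(x * 255)
}

#' @rdname read_image
#' @export
write_image_png <- function(img, path) {
  m <- img_data(img)
  m8 <- round(pmin(pmax(m, 0), 255))
  png::writePNG(m8 / 255, path)
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain-text (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(vals * (255 / maxv), nrow = h, ncol = w, byrow = TRUE)
}

#' Serialize an echo image as PNG plus a geometry sidecar
#'
#' The intensity grid is written as an 8-bit PNG and the associated
#' [fov_geometry()] to `<path>.fov.json`, so the pair round-trips through
#' plain files.
#'
#' @param echo An [echo_image()].
#' @param path PNG path.
#' @return `read_echo_png()` returns an [echo_image()].
#' @export
write_echo_png <- function(echo, path) {
  stopifnot(inherits(echo, "echo_image"))
  write_image_png(echo$data, path)
  write_fov_json(echo$fov, paste0(path, ".fov.json"))
  invisible(path)
}

#' @rdname write_echo_png
#' @export
read_echo_png <- function(path) {
  echo_image(read_image(path), read_fov_json(paste0(path, ".fov.json")))
}
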