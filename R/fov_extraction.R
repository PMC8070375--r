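#' Ultrasound image region (UIR) crop rectangle
#'
#' The UIR is the fixed rectangle of the display that contains the FOV plus
#' its black surround; scanner annotations (patient data, scale bars) live
#' outside it.  Automatic annotation removal is out of scope: the rectangle
#' is configuration, defaulting to the full frame.
#'
#' @param top,left 0-based pixel offsets of the rectangle's top-left corner.
#' @param height,width Positive extents in pixels.
#' @return An object of class `uir_crop`.
#' @export
uir_crop <- function(top, left, height, width) {
  stopifnot(top >= 0, left >= 0, height > 0, width > 0)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "uir_crop")
}

full_frame_crop <- function(img) {
  m <- img_data(img)
  uir_crop(0L, 0L, nrow(m), ncol(m))
}

crop_matrix <- function(img, crop) {
  m <- img_data(img)
  if (crop$top + crop$height > nrow(m) || crop$left + crop$width > ncol(m))
    stop("UIR crop exceeds the frame")
  m[crop$top + seq_len(crop$height), crop$left + seq_len(crop$width),
    drop = FALSE]
}

#' Binarize the ultrasound image region
#'
#' Thresholds the cropped UIR: the mask is TRUE where intensity exceeds
#' `threshold`.  The default threshold 0 assumes a pure black background
#' outside the FOV, which holds for rendered frames; raise it for noisy
#' screenshots.
#'
#' @param frame Matrix or [display_image()], single channel, 8-bit scale.
#' @param crop A [uir_crop()]; default full frame.
#' @param threshold Intensity threshold (mask = intensity > threshold).
#' @return Logical matrix of the crop's shape.
#' @export
binarize_uir <- function(frame, crop = NULL, threshold = 0) {
  m <- img_data(frame)
  if (is.null(crop)) crop <- full_frame_crop(m)
  sub <- crop_matrix(m, crop)
  mask <- sub > threshold
  if (!any(mask)) {
    stop(errorCondition(
      "empty mask: the frame contains no foreground above the threshold",
      class = c("usrsc_no_foreground_error", "usrsc_error")))
  }
  mask
}

# 4-neighbour binary erosion with FALSE padding; boundary = mask & !eroded.
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  er <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  mask & !er
}

# Standard line Hough accumulator over point set (x, y), normal form
# rho = x cos(theta) + y sin(theta), theta in [0, pi) at `theta_step` (rad)
# and `rho_step` (px) resolution.  Returns the accumulator plus bin centres.
hough_accumulate <- function(x, y, theta_step = pi / 180, rho_step = 1) {
  thetas <- seq(0, pi - theta_step / 2, by = theta_step)
  diag_len <- sqrt(max(x)^2 + max(y)^2) + rho_step
  rho_breaks <- seq(-diag_len, diag_len, by = rho_step)
  n_rho <- length(rho_breaks)
  acc <- matrix(0L, nrow = n_rho, ncol = length(thetas))
  for (k in seq_along(thetas)) {
    rho <- x * cos(thetas[k]) + y * sin(thetas[k])
    idx <- as.integer(round((rho + diag_len) / rho_step)) + 1L
    tab <- tabulate(idx, nbins = n_rho)
    acc[, k] <- tab
  }
  list(acc = acc, thetas = thetas,
       rhos = rho_breaks)
}

# Total-least-squares line through points: returns unit direction (pointing
# downwards, uy >= 0) and centroid.
tls_line <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  u <- cbind(x - cx, y - cy)
  sv <- svd(u, nu = 0, nv = 2)
  d <- sv$v[, 1]
  if (d[2] < 0) d <- -d
  list(ux = d[1], uy = d[2], cx = cx, cy = cy)
}

new_boundary_line <- function(theta, rho, support, sdev, cx, cy) {
  theta <- theta %% pi
  structure(list(theta = theta, rho = rho, support = support,
                 angle_from_vertical = sdev, cx = cx, cy = cy),
            class = "boundary_line")
}

#' @export
print.boundary_line <- function(x, ...) {
  cat(sprintf(
    "<boundary_line> %.2f deg from vertical, support %d px\n",
    x$angle_from_vertical * 180 / pi, x$support))
  invisible(x)
}

#' Detect the left and right FOV boundary scanlines
#'
#' Finds the two dominant straight edges that bound the field of view — the
#' first scanline (s1, left boundary between FOV and black region) and the
#' last (sN, right boundary) — with a line Hough transform on the mask's
#' morphological boundary (mask minus its 4-neighbour erosion).  Candidate
#' Hough peaks are refined by a total-least-squares fit to their inlier
#' boundary pixels, then filtered: a line must tilt more than
#' `min_angle_deg` from vertical and its inliers must lie on the matching
#' side of the mask centroid.  The strongest surviving peak on each side is
#' returned.  Fewer than two surviving lines, or a pair closer than
#' `parallel_tol_deg` in direction (no apex), signals a candidate
#' linear-array (rectangular) FOV.
#'
#' @param mask Logical matrix from [binarize_uir()].
#' @param min_angle_deg Minimum tilt from vertical for a boundary candidate
#'   (degrees); vertical edges belong to rectangular FOVs.
#' @param parallel_tol_deg Below this inter-line angle (degrees) the pair is
#'   treated as parallel and rejected.
#' @param theta_step_deg,rho_step Hough accumulator resolution (degrees,
#'   pixels).
#' @param inlier_tol Distance (px) within which a boundary pixel counts as
#'   an inlier of a line.
#' @return A list with elements `s1` and `sN`, each a `boundary_line` with
#'   the line in (angle, signed distance) normal form (`theta` in [0, pi),
#'   `rho`), its `support` (inlier count), tilt from vertical (radians,
#'   signed; negative = left boundary) and inlier centroid.
#' @export
detect_boundary_lines <- function(mask, min_angle_deg = 5,
                                  parallel_tol_deg = 2,
                                  theta_step_deg = 1, rho_step = 1,
                                  inlier_tol = 1.5) {
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  bd <- mask_boundary(mask)
  pts <- which(bd, arr.ind = TRUE)
  x <- as.numeric(pts[, 2] - 1)  # 0-based col
  y <- as.numeric(pts[, 1] - 1)  # 0-based row
  fg <- which(mask, arr.ind = TRUE)
  centroid_x <- mean(fg[, 2] - 1)
  centroid_y <- mean(fg[, 1] - 1)

  hg <- hough_accumulate(x, y, theta_step = theta_step_deg * pi / 180,
                         rho_step = rho_step)
  acc <- hg$acc
  no_lines <- function() stop(errorCondition(
    "no convex/sector boundary pair found (candidate linear FOV)",
    class = c("usrsc_no_sector_boundary_error", "usrsc_error")))

  best <- list(left = NULL, right = NULL)
  max_peaks <- 12L
  for (p in seq_len(max_peaks)) {
    m <- which.max(acc)
    if (acc[m] < 10L) break          # too little support to be a boundary
    ti <- (m - 1L) %/% nrow(acc) + 1L
    ri <- m - (ti - 1L) * nrow(acc)
    theta <- hg$thetas[ti]; rho <- hg$rhos[ri]
    # suppress a neighbourhood (+-4 deg, +-6 px) around the accepted peak
    tspan <- which(abs(outer_angle_diff(hg$thetas, theta)) <=
                     4.5 * pi / 180)
    rspan <- which(abs(hg$rhos - rho) <= 6)
    acc[rspan, tspan] <- 0L
    # inliers of the coarse line, refined by TLS (one reweighting pass)
    for (it in 1:2) {
      d <- abs(x * cos(theta) + y * sin(theta) - rho)
      inl <- d <= inlier_tol
      if (sum(inl) < 10L) break
      fit <- tls_line(x[inl], y[inl])
      # back to normal form: normal = direction rotated by 90 deg
      theta <- atan2(fit$ux, -fit$uy) %% pi
      rho <- fit$cx * cos(theta) + fit$cy * sin(theta)
    }
    if (sum(inl) < 10L) next
    fit <- tls_line(x[inl], y[inl])
    # boundary pixels are the outermost *foreground* layer, whose centres sit
    # up to a pixel inside the true edge; shift the fitted line half a pixel
    # outward (away from the foreground centroid) to debias the apex
    s <- sign(centroid_x * cos(theta) + centroid_y * sin(theta) - rho)
    rho <- rho - 0.5 * s
    sdev <- atan2(fit$ux, fit$uy)    # signed tilt from vertical (down axis)
    if (abs(sdev) < min_angle_deg * pi / 180) next
    if (abs(sdev) > 85 * pi / 180) next   # near-horizontal: arc chord
    side <- if (sdev < 0) "left" else "right"
    ok_side <- (side == "left" && fit$cx <= centroid_x) ||
      (side == "right" && fit$cx >= centroid_x)
    if (!ok_side) next
    cand <- new_boundary_line(theta, rho, support = sum(inl), sdev = sdev,
                              cx = fit$cx, cy = fit$cy)
    if (is.null(best[[side]]) || cand$support > best[[side]]$support)
      best[[side]] <- cand
    if (!is.null(best$left) && !is.null(best$right)) break
  }
  if (is.null(best$left) || is.null(best$right)) no_lines()
  dang <- best$right$angle_from_vertical - best$left$angle_from_vertical
  if (dang < parallel_tol_deg * pi / 180) no_lines()
  list(s1 = best$left, sN = best$right)
}

# absolute angular difference on the [0, pi) circle
outer_angle_diff <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

line_intersection <- function(l1, l2) {
  a <- rbind(c(cos(l1$theta), sin(l1$theta)),
             c(cos(l2$theta), sin(l2$theta)))
  b <- c(l1$rho, l2$rho)
  det <- a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1]
  if (abs(det) < 1e-12) return(NULL)
  as.numeric(solve(a, b))
}

#' Estimate field-of-view geometry from a display frame
#'
#' Recovers the full [fov_geometry()] of a convex or sector frame: the UIR
#' is binarized, the two boundary scanlines are detected
#' ([detect_boundary_lines()]), the apex is their intersection and the
#' opening angle `theta_c` the angle between them.  Radii are then read off
#' the foreground: `r_c` is the minimum apex distance over foreground pixel
#' centres, `r_c + d_c` the maximum.  The geometry is classified `sector`
#' when `r_c < r_sector_max`, else `convex`; when no boundary pair exists
#' (vertical/parallel edges) the estimator falls back to `kind = "linear"`
#' with the foreground bounding box as rectangular geometry.  Offsets are
#' reported in full-frame coordinates.  The procedure is deterministic.
#'
#' @inheritParams binarize_uir
#' @param r_sector_max Below this estimated `r_c` (px) the FOV is called
#'   `sector` and its radius snapped to the apex.
#' @param ... Passed to [detect_boundary_lines()].
#' @return A [fov_geometry()].
#' @examples
#' spec <- phantom_spec(c(160, 128), seed = 7)
#' ph <- generate_echo_phantom(spec,
#'   fov_geometry(0, 0, 80, 60 * pi / 180, 300))
#' fr <- render_display_frame(ph, canvas = c(450, 520))
#' estimate_fov_geometry(fr$frame)
#' @export
estimate_fov_geometry <- function(frame, crop = NULL, threshold = 0,
                                  r_sector_max = 5, ...) {
  m <- img_data(frame)
  if (is.null(crop)) crop <- full_frame_crop(m)
  mask <- binarize_uir(m, crop, threshold)
  lines <- tryCatch(detect_boundary_lines(mask, ...),
                    usrsc_no_sector_boundary_error = function(e) NULL)
  fg <- which(mask, arr.ind = TRUE)
  fx <- fg[, 2] - 1 + crop$left
  fy <- fg[, 1] - 1 + crop$top
  if (is.null(lines)) {
    return(fov_geometry(min(fx), min(fy), r_c = 0, theta_c = NA,
                        d_c = max(fy) - min(fy) + 1, kind = "linear",
                        width = max(fx) - min(fx) + 1))
  }
  apex <- line_intersection(lines$s1, lines$sN)
  if (is.null(apex)) {
    return(fov_geometry(min(fx), min(fy), r_c = 0, theta_c = NA,
                        d_c = max(fy) - min(fy) + 1, kind = "linear",
                        width = max(fx) - min(fx) + 1))
  }
  theta_c <- lines$sN$angle_from_vertical - lines$s1$angle_from_vertical
  x_offset <- apex[1] + crop$left
  y_offset <- apex[2] + crop$top
  rho <- sqrt((fx - x_offset)^2 + (fy - y_offset)^2)
  r_c <- min(rho)
  d_c <- max(rho) - r_c
  kind <- if (r_c < r_sector_max) "sector" else "convex"
  if (kind == "sector") r_c <- 0
  fov_geometry(x_offset, y_offset, r_c, theta_c, d_c, kind = kind)
}
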