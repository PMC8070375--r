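#' Configuration for the training-set builder
#'
#' @param crop A [uir_crop()] or NULL for full frame.
#' @param threshold Binarization threshold for geometry estimation.
#' @param out_shape Final image size, default `c(64, 64)` — the network
#'   input size.
#' @param rsc_shape Intermediate polar-grid resolution before the final
#'   resize (radial samples x scanlines).
#' @param variant Which outputs to build: `"rsc"` (reverse-scan-converted
#'   polar images), `"usi"` (display-region crops downsampled directly, the
#'   comparison baseline), or `"both"`.
#' @param geometry Optional [fov_geometry()] to use for every frame,
#'   skipping estimation.
#' @param per_frame_geometry If TRUE estimate geometry for every frame;
#'   default FALSE estimates once from the first usable frame and reuses it
#'   (a scanner with one probe has a fixed FOV shape across a session).
#' @return A list of class `builder_config`.
#' @export
builder_config <- function(crop = NULL, threshold = 0,
                           out_shape = c(64L, 64L),
                           rsc_shape = c(256L, 256L),
                           variant = c("both", "rsc", "usi"),
                           geometry = NULL, per_frame_geometry = FALSE) {
  variant <- match.arg(variant)
  if (!is.null(geometry)) stopifnot(inherits(geometry, "fov_geometry"))
  structure(list(crop = crop, threshold = threshold,
                 out_shape = as.integer(out_shape),
                 rsc_shape = as.integer(rsc_shape), variant = variant,
                 geometry = geometry,
                 per_frame_geometry = isTRUE(per_frame_geometry)),
            class = "builder_config")
}

#' Build a fixed-size training set from labeled display frames
#'
#' The end-to-end preprocessing pipeline: for each input frame, crop the
#' ultrasound image region, estimate (or accept) the FOV geometry, reverse
#' scan convert to the polar grid, and downsample to the network input size.
#' The `usi` variant skips the geometric step — the cropped display region
#' is downsampled directly — providing the baseline representation in which
#' the FOV outline itself remains visible to a classifier.  Frames that
#' fail any step are recorded as `skipped:<reason>` and never abort the
#' batch.  The pipeline is a pure function of its inputs and configuration:
#' re-runs are bit-identical.
#'
#' @param input_manifest data.frame with columns `file` (readable image
#'   path) and `label`; extra columns are ignored.
#' @param config A [builder_config()].
#' @param out_dir Output directory for the built images (PNG) and
#'   `dataset.csv` manifest.
#' @return The output manifest data.frame: `source`, `label`, `variant`,
#'   `output`, `status`, plus the geometry columns used (NA when skipped).
#' @export
build_training_set <- function(input_manifest, config = builder_config(),
                               out_dir) {
  if (!is.data.frame(input_manifest) || nrow(input_manifest) == 0)
    stop("input manifest is empty")
  stopifnot(all(c("file", "label") %in% names(input_manifest)),
            inherits(config, "builder_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  variants <- if (config$variant == "both") c("rsc", "usi") else config$variant
  shared_fov <- config$geometry
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(input_manifest))) {
    src <- input_manifest$file[i]
    label <- input_manifest$label[i]
    frame <- tryCatch(read_image(src), error = function(e) e)
    for (v in variants) {
      k <- k + 1L
      out <- file.path(out_dir, sprintf(
        "%s_%s.png", sub("\\.[^.]+$", "", basename(src)), v))
      res <- tryCatch({
        if (inherits(frame, "error")) stop("unreadable-source")
        crop <- if (is.null(config$crop)) full_frame_crop(frame)
                else config$crop
        if (v == "usi") {
          img <- downsample_image(crop_matrix(frame, crop),
                                  config$out_shape)
          list(img = img, fov = NULL)
        } else {
          fov <- if (!is.null(config$geometry)) config$geometry
          else if (!config$per_frame_geometry && !is.null(shared_fov))
            shared_fov
          else estimate_fov_geometry(frame, crop, config$threshold)
          if (!config$per_frame_geometry && is.null(shared_fov))
            shared_fov <- fov
          img <- if (fov$kind == "linear") {
            crop_resize_linear(frame, fov, config$out_shape)
          } else {
            downsample_image(
              reverse_scan_convert(frame, fov, config$rsc_shape)$data,
              config$out_shape)
          }
          list(img = img, fov = fov)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        reason <- if (inherits(res, "usrsc_no_foreground_error"))
          "no-foreground"
        else if (identical(conditionMessage(res), "unreadable-source"))
          "unreadable-source"
        else gsub("[^a-z0-9-]+", "-", tolower(conditionMessage(res)))
        rows[[k]] <- manifest_row(src, label, v, NA_character_,
                                  paste0("skipped:", reason), NULL)
        next
      }
      write_image_png(res$img, out)
      rows[[k]] <- manifest_row(src, label, v, out, "ok", res$fov)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "dataset.csv"),
                   row.names = FALSE)
  manifest
}

manifest_row <- function(src, label, variant, output, status, fov) {
  data.frame(
    source = src, label = label, variant = variant, output = output,
    status = status,
    kind = if (is.null(fov)) NA_character_ else fov$kind,
    x_offset = if (is.null(fov)) NA_real_ else fov$x_offset,
    y_offset = if (is.null(fov)) NA_real_ else fov$y_offset,
    r_c = if (is.null(fov)) NA_real_ else fov$r_c,
    theta_c_deg = if (is.null(fov)) NA_real_ else fov$theta_c * 180 / pi,
    d_c = if (is.null(fov)) NA_real_ else fov$d_c,
    stringsAsFactors = FALSE)
}
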