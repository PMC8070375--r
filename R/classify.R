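#' Compare representations with a reference classifier
#'
#' Trains a random forest (via \pkg{ranger}) on the flattened pixels of the
#' built training images, separately per variant, and reports held-out
#' accuracy.  This is a harness for comparing the polar (`rsc`) and display
#' (`usi`) representations of the same frames — a lightweight stand-in for
#' a CNN study, not a recommended organ classifier.
#'
#' @param manifest Output of [build_training_set()] containing both
#'   variants with `status == "ok"`.
#' @param train_frac Fraction of frames per class used for training; the
#'   split is stratified by label and shared across variants so both see
#'   identical train/test frames.
#' @param seed Integer seed for the split and the forest.
#' @param num_trees Trees in the forest.
#' @return A list with per-variant held-out accuracy in percent (e.g.
#'   `$rsc`, `$usi`).
#' @export
classifier_accuracy_by_variant <- function(manifest, train_frac = 0.7,
                                           seed = 1L, num_trees = 200L) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("classifier_accuracy_by_variant() needs the `ranger` package")
  ok <- manifest[manifest$status == "ok", ]
  variants <- unique(ok$variant)
  sources <- unique(ok$source)
  labels <- ok$label[match(sources, ok$source)]
  split <- with_local_seed(seed, {
    train <- logical(length(sources))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      train[sample(idx, max(1L, round(train_frac * length(idx))))] <- TRUE
    }
    train
  })
  out <- list()
  for (v in variants) {
    rows <- ok[ok$variant == v, ]
    rows <- rows[match(sources, rows$source), ]
    n_px <- length(read_image(rows$output[1]))
    x <- t(vapply(rows$output, function(f) as.vector(read_image(f)),
                  numeric(n_px)))
    df <- data.frame(label = factor(labels), x)
    fit <- with_local_seed(seed + 1L, ranger::ranger(
      label ~ ., data = df[split, ], num.trees = num_trees,
      seed = seed + 1L))
    pred <- stats::predict(fit, df[!split, ])$predictions
    out[[v]] <- 100 * mean(pred == df$label[!split])
  }
  out
}
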