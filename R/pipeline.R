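#' Run the full image-classification pipeline
#'
#' End to end: load the class-labeled image directory, preprocess, extract
#' features with the configured extractor, then hand the feature matrix to
#' [qga_select()] — which performs the stratified 80/20 split, the QGA subset
#' search on the training portion, retrains the classifier head on the
#' selected features and evaluates once on the held-out portion.
#'
#' @param image_dir Directory with one subdirectory per class.
#' @param extractor A `"feature_extractor"`; defaults to
#'   [random_projection_extractor()] matched to `size`.
#' @param config An [fs_config()].
#' @param size Preprocessing side length (default 128).
#' @return An object of class `"qga_pipeline"`: list with `selection` (the
#'   `"qgafs"` result), `report` (held-out metrics), `class_names`, `n`,
#'   `d`, `extractor_tag`.
#' @export
run_pipeline <- function(image_dir, extractor = NULL, config = fs_config(),
                         size = 128) {
  dataset <- load_image_dir(image_dir, size = size)
  if (dataset$n_classes < 2)
    stop("pipeline needs at least 2 classes, found ", dataset$n_classes)
  if (is.null(extractor))
    extractor <- random_projection_extractor(size = size)
  fm <- extract_features(dataset, extractor)
  sel <- qga_select(fm, config)
  structure(list(selection = sel, report = sel$report,
                 class_names = dataset$class_names,
                 n = dataset$n, d = fm$d,
                 extractor_tag = extractor$tag),
            class = "qga_pipeline")
}

#' @export
print.qga_pipeline <- function(x, ...) {
  cat("Image classification pipeline (", x$n, " images, ",
      length(x$class_names), " classes, ", x$d, " features via ",
      x$extractor_tag, ")\n", sep = "")
  print(x$selection)
  invisible(x)
}
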