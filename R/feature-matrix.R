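#' Construct a feature matrix with class labels
#'
#' The container passed between feature extraction, selection and the
#' classifier head: an `n x d` numeric matrix plus integer class labels in
#' `0..C-1`. Labels must cover a contiguous range and every represented class
#' needs at least two samples; non-finite feature values are rejected.
#'
#' @param x Numeric `n x d` matrix (or coercible data frame).
#' @param labels Integer labels `0..C-1` (or a factor, converted).
#' @param feature_names Optional length-`d` character vector; defaults to
#'   `f000, f001, ...`.
#' @param informative Optional length-`d` logical ground-truth mask (known
#'   informative columns of synthetic data).
#' @param class_names Optional length-`C` character vector.
#' @return An object of class `"feature_matrix"`: list with `x`, `y`,
#'   `feature_names`, `informative`, `class_names`, `n`, `d`, `n_classes`.
#' @export
feature_matrix <- function(x, labels, feature_names = NULL,
                           informative = NULL, class_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(labels) - 1L
  }
  y <- as.integer(labels)
  if (length(y) != nrow(x)) stop("labels length does not match row count")
  if (any(is.na(y)) || any(y < 0)) stop("labels must be integers in 0..C-1")
  C <- max(y) + 1L
  counts <- tabulate(y + 1L, nbins = C)
  if (any(counts == 0))
    stop("labels must cover the contiguous range 0..", C - 1L)
  if (any(counts < 2))
    stop("every class needs at least 2 samples")
  if (is.null(feature_names))
    feature_names <- sprintf("f%03d", seq_len(ncol(x)) - 1L)
  if (length(feature_names) != ncol(x))
    stop("feature_names length does not match column count")
  if (!is.null(informative) && length(informative) != ncol(x))
    stop("informative mask length does not match column count")
  colnames(x) <- feature_names
  structure(list(x = x, y = y, feature_names = feature_names,
                 informative = informative,
                 class_names = class_names %||% as.character(0:(C - 1L)),
                 n = nrow(x), d = ncol(x), n_classes = C),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", x$n, " samples x ", x$d, " features, ",
      x$n_classes, " classes\n", sep = "")
  cat("  class counts: ",
      paste(x$class_names, tabulate(x$y + 1L, x$n_classes), sep = "=",
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$informative))
    cat("  known informative features: ", sum(x$informative), "\n", sep = "")
  invisible(x)
}

#' Subset the columns of a feature matrix by a bit mask
#'
#' Returns the column subset selected by `mask`, preserving row order,
#' labels and feature names. An all-zero mask is an error: an empty matrix
#' cannot be trained on.
#'
#' @param fm A [feature_matrix()].
#' @param mask Logical or 0/1 vector of length `d`.
#' @return A [feature_matrix()] with the selected columns.
#' @export
apply_mask <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"))
  mask <- as_mask(mask)
  if (length(mask) != fm$d)
    stop("mask length (", length(mask), ") does not match feature count (",
         fm$d, ")")
  if (!any(mask)) stop("all-zero mask selects no features")
  feature_matrix(fm$x[, mask, drop = FALSE], fm$y,
                 feature_names = fm$feature_names[mask],
                 informative = fm$informative[mask],
                 class_names = fm$class_names)
}

as_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  m <- as.integer(mask)
  if (any(is.na(m)) || any(!m %in% c(0L, 1L)))
    stop("mask must be logical or 0/1")
  m == 1L
}

subset_rows <- function(fm, idx) {
  feature_matrix(fm$x[idx, , drop = FALSE], fm$y[idx],
                 feature_names = fm$feature_names,
                 informative = fm$informative,
                 class_names = fm$class_names)
}

#' Read / write delimited feature matrices
#'
#' The on-disk interchange format is comma-separated text: one header row of
#' feature names plus a final `label` column of integer class labels. For
#' speed, `format = "rds"` round-trips the object through R's native
#' serialization instead.
#'
#' @param path File path.
#' @param fm A [feature_matrix()].
#' @param format `"csv"` (default) or `"rds"`.
#' @return `read_features()` returns a [feature_matrix()];
#'   `write_features()` returns `path` invisibly.
#' @export
read_features <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    fm <- readRDS(path)
    stopifnot(inherits(fm, "feature_matrix"))
    return(fm)
  }
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  if (!"label" %in% names(df))
    stop("parse error in '", path, "': no `label` column in header (line 1)")
  y <- df$label
  xs <- df[setdiff(names(df), "label")]
  if (!ncol(xs)) stop("parse error in '", path, "': no feature columns")
  for (j in seq_along(xs)) {
    if (!is.numeric(xs[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(xs[[j]]))))[1]
      stop("parse error in '", path, "': non-numeric value in column '",
           names(xs)[j], "' (line ", bad + 1L, ")")
    }
  }
  feature_matrix(as.matrix(xs), y, feature_names = names(xs))
}

#' @rdname read_features
#' @export
write_features <- function(fm, path, format = c("csv", "rds")) {
  stopifnot(inherits(fm, "feature_matrix"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(fm, path)
  } else {
    df <- as.data.frame(fm$x)
    names(df) <- fm$feature_names
    df$label <- fm$y
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Stratified assignment of rows to k folds: within each class, shuffled
# members are dealt round-robin, so every fold's training side contains each
# class whenever the class has >= k members.
stratified_folds <- function(y, k) {
  if (k < 2) stop("`folds` must be >= 2")
  counts <- tabulate(y + 1L)
  if (any(counts < k))
    stop("class ", which(counts < k)[1] - 1L, " has ", min(counts),
         " samples; cannot build ", k,
         " stratified folds (reduce `folds`)")
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- sample(which(y == c))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split; returns the test-row indices.
stratified_holdout <- function(y, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("split fraction must be in (0, 1)")
  idx <- unlist(lapply(unique(y), function(c) {
    rows <- which(y == c)
    sample(rows, max(1L, round(length(rows) * fraction)))
  }))
  sort(idx)
}
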