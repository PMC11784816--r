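#' Preprocess an image to the network input contract
#'
#' Brings an arbitrary grayscale or RGB raster to the standard input
#' representation: bilinear resize to `size x size`, grayscale replicated to
#' three channels, integer `0..255` pixel values divided by 255, and values
#' clipped to `[0, 1]`. Idempotent: an already conforming image passes
#' through unchanged.
#'
#' @param img 2-D matrix (grayscale) or `H x W x {1,3,4}` array (an alpha
#'   channel is dropped). Integer `0..255` or real `[0, 1]` values.
#' @param size Target side length (default 128).
#' @return A `size x size x 3` array with values in `[0, 1]`.
#' @export
preprocess_image <- function(img, size = 128) {
  if (!is.numeric(img)) stop("image must be a numeric array")
  a <- as.array(img)
  nd <- length(dim(a))
  if (nd == 2) a <- array(a, c(dim(a), 1L))
  else if (nd != 3) stop("non-image shape: expected 2-D or 3-D array")
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  if (!dim(a)[3] %in% c(1L, 3L))
    stop("non-image shape: ", dim(a)[3], " channels")
  if (is.integer(img) || max(a) > 1) a <- a / 255
  if (dim(a)[1] != size || dim(a)[2] != size) {
    a <- array(apply(a, 3, function(ch)
      as.array(EBImage::resize(EBImage::Image(ch), w = size, h = size,
                               filter = "bilinear"))),
      c(size, size, dim(a)[3]))
  }
  if (dim(a)[3] == 1L) a <- array(a[, , 1], c(size, size, 3L))
  a[a < 0] <- 0
  a[a > 1] <- 1
  a
}

#' Load a class-labeled image directory
#'
#' Expects one subdirectory per class containing PNG/JPEG/TIFF images (the
#' usual layout of labeled image collections). Classes are ordered
#' lexicographically and labeled `0..C-1`; every image is preprocessed with
#' [preprocess_image()] (grayscale sources are replicated to 3 channels).
#' Unreadable files are skipped with a warning and counted.
#'
#' @param root Directory with one subdirectory per class.
#' @param size Preprocessing target side length (default 128).
#' @return An object of class `"image_dataset"`: list with `images` (list of
#'   `size x size x 3` arrays in `[0, 1]`), `labels` (integers `0..C-1`),
#'   `class_names`, `paths`, `n`, `n_classes`, `n_skipped`.
#' @export
load_image_dir <- function(root, size = 128) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (!length(classes)) stop("empty root: no class subdirectories in ", root)
  images <- list(); labels <- integer(); paths <- character()
  n_skipped <- 0L
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[ci]),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    ok <- 0L
    for (f in files) {
      img <- tryCatch(as.array(EBImage::readImage(f)),
                      error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- preprocess_image(img, size)
      labels <- c(labels, ci - 1L)
      paths <- c(paths, f)
      ok <- ok + 1L
    }
    if (ok == 0L)
      stop("class '", classes[ci], "' has no readable images")
  }
  structure(list(images = images, labels = labels, class_names = classes,
                 paths = paths, n = length(images),
                 n_classes = length(classes), n_skipped = n_skipped),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("Image dataset: ", x$n, " images, ", x$n_classes, " classes (",
      paste(x$class_names, collapse = ", "), ")\n", sep = "")
  if (x$n_skipped) cat("  skipped unreadable files: ", x$n_skipped, "\n")
  invisible(x)
}

#' Seeded random-projection feature extractor
#'
#' A deterministic stand-in for a pretrained convolutional backbone,
#' satisfying the same contract: a fixed mapping from a preprocessed image to
#' a length-`d` real feature vector. The map is a seeded random Gaussian
#' projection of the flattened pixels followed by rectification (ReLU), which
#' preserves linear class separability of the pixel space with high
#' probability. The projection matrix is frozen at construction, so the same
#' image always yields the same vector.
#'
#' @param d Output dimension.
#' @param size Expected input side length (images are `size x size x 3`).
#' @param seed Seed for the projection matrix.
#' @return An object of class `"feature_extractor"`: list with `d`, `fun`
#'   (image array -> numeric vector), and an identity `tag`.
#' @export
random_projection_extractor <- function(d = 64, size = 128, seed = 42) {
  if (d < 1) stop("`d` must be >= 1")
  p <- as.integer(size) * as.integer(size) * 3L
  set.seed(seed)
  W <- matrix(stats::rnorm(d * p, sd = 1 / sqrt(p)), d, p)
  b <- stats::rnorm(d, sd = 0.01)
  fun <- function(img) {
    v <- as.numeric(img)
    if (length(v) != p)
      stop("extractor expects a ", size, "x", size, "x3 image")
    pmax(0, drop(W %*% v) + b)
  }
  structure(list(d = as.integer(d), fun = fun,
                 tag = sprintf("random_projection(d=%d,size=%d,seed=%d)",
                               d, size, seed)),
            class = "feature_extractor")
}

#' Extract a feature matrix from an image dataset
#'
#' Applies the extractor to every image, preserving row order and carrying
#' the labels through. The extractor's declared output dimension is enforced.
#'
#' @param dataset An [load_image_dir()] / `"image_dataset"` object.
#' @param extractor A `"feature_extractor"`, e.g.
#'   [random_projection_extractor()].
#' @return A [feature_matrix()] with `n` rows and `extractor$d` columns.
#' @export
extract_features <- function(dataset, extractor) {
  stopifnot(inherits(dataset, "image_dataset"),
            inherits(extractor, "feature_extractor"))
  if (dataset$n == 0) stop("empty dataset: no images to extract from")
  rows <- lapply(dataset$images, function(im) {
    v <- extractor$fun(im)
    if (!is.numeric(v) || length(v) != extractor$d)
      stop("extractor contract violation: returned length ", length(v),
           ", declared d = ", extractor$d)
    as.numeric(v)
  })
  x <- do.call(rbind, rows)
  feature_matrix(x, dataset$labels, class_names = dataset$class_names)
}

#' Classifier-head training configuration
#'
#' Hyperparameters of the softmax classifier head trained on (selected)
#' features: one rectified hidden layer, dropout regularization, Adam
#' optimization with early stopping and learning-rate reduction on plateau
#' of the validation loss.
#'
#' @param hidden Hidden-layer width (default 128).
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Epoch cap (default 50).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 5).
#' @param plateau_patience Epochs without validation-loss improvement before
#'   the learning rate is multiplied by `plateau_factor` (default 5).
#' @param plateau_factor Learning-rate reduction factor (default 0.5).
#' @param validation_fraction Stratified fraction of the training data held
#'   out for the validation-loss callbacks (default 0.1).
#' @param seed Seed for weight initialization, shuffling and dropout masks.
#' @return A list of class `"head_config"`.
#' @export
head_config <- function(hidden = 128, dropout = 0.5, learning_rate = 0.001,
                        batch_size = 32, max_epochs = 50, patience = 5,
                        plateau_patience = 5, plateau_factor = 0.5,
                        validation_fraction = 0.1, seed = 1) {
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  stopifnot(hidden >= 1, learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, plateau_patience >= 1,
            plateau_factor > 0, plateau_factor < 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "head_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the softmax classifier head
#'
#' Trains `input -> dense(hidden, ReLU) -> dropout -> softmax(C)` by
#' minibatch Adam on the cross-entropy loss. A stratified validation split is
#' carved from the training data for the callbacks: early stopping when the
#' validation loss has not improved for `patience` epochs (the best-epoch
#' weights are restored) and learning-rate reduction on plateau. Fully
#' deterministic given `config$seed`.
#'
#' @param fm Training [feature_matrix()] (at least 2 classes).
#' @param config A [head_config()].
#' @return An object of class `"softmax_head"`: weights, `history` (data
#'   frame: epoch, train_loss, val_loss, lr), `n_classes`, `d`, `config`.
#'   Use [predict.softmax_head()] for probabilities or class labels.
#' @export
train_head <- function(fm, config = head_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "head_config"))
  if (fm$n_classes < 2) stop("head training needs at least 2 classes")
  set.seed(config$seed)

  val_idx <- stratified_holdout(fm$y, config$validation_fraction)
  tr_idx <- setdiff(seq_len(fm$n), val_idx)
  X <- fm$x[tr_idx, , drop = FALSE]; y <- fm$y[tr_idx]
  Xv <- fm$x[val_idx, , drop = FALSE]; yv <- fm$y[val_idx]
  n <- nrow(X); d <- ncol(X); C <- fm$n_classes
  Y <- diag(C)[y + 1L, , drop = FALSE]

  h <- config$hidden
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * C, sd = sqrt(1 / h)), h, C)
  b2 <- numeric(C)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0

  ce_loss <- function(P, Y) -mean(log(pmax(rowSums(P * Y), 1e-12)))
  val_loss_of <- function(pp) {
    Hv <- pmax(sweep(Xv %*% pp$W1, 2, pp$b1, "+"), 0)
    Pv <- softmax_rows(sweep(Hv %*% pp$W2, 2, pp$b2, "+"))
    ce_loss(Pv, diag(C)[yv + 1L, , drop = FALSE])
  }

  lr <- config$learning_rate
  best_val <- Inf; best_params <- params
  since_improve <- 0L; since_plateau <- 0L
  history <- NULL

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batch <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      nb <- length(idx)

      Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
      H <- pmax(Z1, 0)
      if (config$dropout > 0) {
        keep <- matrix(stats::runif(nb * h) >= config$dropout, nb, h)
        H <- H * keep / (1 - config$dropout)
      }
      P <- softmax_rows(sweep(H %*% params$W2, 2, params$b2, "+"))
      ep_loss <- ep_loss + ce_loss(P, Yb); n_batch <- n_batch + 1

      dZ2 <- (P - Yb) / nb
      gW2 <- crossprod(H, dZ2); gb2 <- colSums(dZ2)
      dH <- dZ2 %*% t(params$W2)
      if (config$dropout > 0) dH <- dH * keep / (1 - config$dropout)
      dZ1 <- dH * (Z1 > 0)
      gW1 <- crossprod(Xb, dZ1); gb1 <- colSums(dZ1)

      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1
      for (k in names(params)) {
        adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * grads[[k]]
        adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- adam_m[[k]] / (1 - beta1^step)
        vhat <- adam_v[[k]] / (1 - beta2^step)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }

    vl <- val_loss_of(params)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / n_batch,
                                val_loss = vl, lr = lr))
    if (vl < best_val - 1e-8) {
      best_val <- vl; best_params <- params
      since_improve <- 0L; since_plateau <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_plateau <- since_plateau + 1L
      if (since_plateau >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        since_plateau <- 0L
      }
      if (since_improve >= config$patience) break
    }
  }

  structure(list(W1 = best_params$W1, b1 = best_params$b1,
                 W2 = best_params$W2, b2 = best_params$b2,
                 history = history, n_classes = C, d = d,
                 class_names = fm$class_names, config = config),
            class = "softmax_head")
}

#' Predict from a trained softmax head
#'
#' @param object A `"softmax_head"` from [train_head()].
#' @param newdata A [feature_matrix()] or numeric matrix with `d` columns.
#' @param type `"class"` (integer labels `0..C-1`) or `"prob"`
#'   (`n x C` probability matrix).
#' @param ... Unused.
#' @return Predicted labels or probabilities.
#' @export
predict.softmax_head <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_matrix")) newdata$x
       else as.matrix(newdata)
  if (ncol(X) != object$d)
    stop("newdata has ", ncol(X), " features; head expects ", object$d)
  H <- pmax(sweep(X %*% object$W1, 2, object$b1, "+"), 0)
  P <- softmax_rows(sweep(H %*% object$W2, 2, object$b2, "+"))
  if (type == "prob") return(P)
  max.col(P, ties.method = "first") - 1L
}

#' @export
print.softmax_head <- function(x, ...) {
  cat("Softmax classifier head: ", x$d, " -> ", x$config$hidden, " -> ",
      x$n_classes, " (dropout ", x$config$dropout, ")\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best validation loss ",
      format(min(x$history$val_loss), digits = 4), "\n", sep = "")
  invisible(x)
}
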