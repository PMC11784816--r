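#' Feature-selection (QGA-FS) configuration
#'
#' Bundles everything the wrapper needs: the embedded QGA settings, the
#' lightweight surrogate classifier scoring candidate subsets, the
#' cross-validation fold count, the sparsity penalty, the held-out test
#' fraction, and the master seed from which all sub-seeds (split, folds,
#' QGA, head) are derived.
#'
#' @param qga A [qga_config()] for the subset search.
#' @param classifier Surrogate classifier inside the fitness function:
#'   `"lda"` (linear discriminant analysis, default) or `"multinom"`
#'   (multinomial logistic regression).
#' @param folds Stratified cross-validation folds for the fitness (>= 2,
#'   default 5).
#' @param lambda Sparsity penalty weight: fitness is mean CV accuracy minus
#'   `lambda * (selected / d)`. Default 0.01.
#' @param test_fraction Stratified held-out fraction, touched only by the
#'   final evaluation (default 0.2).
#' @param head A [head_config()] for the final classifier retrained on the
#'   selected features.
#' @param seed Master seed.
#' @return A list of class `"fs_config"`.
#' @export
fs_config <- function(qga = qga_config(), classifier = c("lda", "multinom"),
                      folds = 5, lambda = 0.01, test_fraction = 0.2,
                      head = head_config(), seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(qga, "qga_config"), inherits(head, "head_config"))
  if (folds < 2) stop("`folds` must be >= 2")
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)")
  structure(list(qga = qga, classifier = classifier,
                 folds = as.integer(folds), lambda = lambda,
                 test_fraction = test_fraction, head = head,
                 seed = as.integer(seed)),
            class = "fs_config")
}

# Deterministic fan-out of the master seed into sub-seeds (split, QGA, head).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

# Columns with (near-)zero variance carry no usable signal and break lda;
# they are dropped from the probe fit (the mask itself is unchanged).
live_columns <- function(x) {
  keep <- apply(x, 2, stats::sd) > 1e-10
  if (!any(keep)) stop("all selected features are constant")
  keep
}

fit_probe <- function(x, y, classifier) {
  if (classifier == "lda") {
    keep <- live_columns(x)
    model <- suppressWarnings(MASS::lda(x[, keep, drop = FALSE],
                                        grouping = factor(y)))
    attr(model, "keep") <- keep
    model
  } else {
    df <- data.frame(.y = factor(y), x)
    suppressWarnings(nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                    MaxNWts = 10000))
  }
}

predict_probe <- function(model, x, classifier) {
  if (classifier == "lda") {
    keep <- attr(model, "keep")
    as.integer(as.character(
      stats::predict(model, x[, keep, drop = FALSE])$class))
  } else {
    as.integer(as.character(stats::predict(model,
                                           newdata = data.frame(x))))
  }
}

#' Fitness of a feature subset
#'
#' Scores a candidate mask by stratified k-fold cross-validated accuracy of
#' the surrogate classifier on the masked columns, minus the sparsity
#' penalty `lambda * (selected / d)`. The all-zero mask scores 0 (the
#' defined floor) without any training, keeping the fitness total. A mask on
#' which the surrogate cannot be fit (e.g. a feature constant within every
#' class) also scores 0.
#'
#' @param fm Training [feature_matrix()].
#' @param mask Logical or 0/1 vector of length `d`.
#' @param config An [fs_config()].
#' @param folds Optional precomputed fold assignment (integer vector,
#'   values `1..config$folds`), so repeated calls score different masks on
#'   identical folds. When `NULL`, folds are drawn from `config$seed`.
#' @return Penalized mean CV accuracy (higher is better).
#' @export
subset_fitness <- function(fm, mask, config = fs_config(), folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "fs_config"))
  mask <- as_mask(mask)
  if (length(mask) != fm$d) stop("mask length does not match feature count")
  if (!any(mask)) return(0)
  if (is.null(folds)) {
    set.seed(derive_seed(config$seed, 0L))
    folds <- stratified_folds(fm$y, config$folds)
  }
  x <- fm$x[, mask, drop = FALSE]
  acc <- vapply(seq_len(config$folds), function(f) {
    tr <- folds != f
    model <- tryCatch(fit_probe(x[tr, , drop = FALSE], fm$y[tr],
                                config$classifier),
                      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    pred <- predict_probe(model, x[!tr, , drop = FALSE], config$classifier)
    mean(pred == fm$y[!tr])
  }, numeric(1))
  if (anyNA(acc)) return(0)
  mean(acc) - config$lambda * mean(mask)
}

#' Select features with the quantum genetic algorithm (QGA-FS)
#'
#' The wrapper pipeline stage: the data are split into a stratified training
#' portion and a held-out test portion; the QGA searches over feature masks
#' of length `d`, each scored by [subset_fitness()] on the training portion
#' only (folds fixed once, so the fitness landscape is deterministic); the
#' final classifier head is retrained on the training portion restricted to
#' the best mask; and the held-out portion is evaluated exactly once, by
#' that final model. Held-out rows never influence the search.
#'
#' @param fm A [feature_matrix()] with `d >= 2`.
#' @param config An [fs_config()].
#' @return An object of class `"qgafs"`: list with `mask` (logical), `bits`,
#'   `selected` (feature names), `n_selected`, `run` (the underlying
#'   `"qga_run"` with the fitness trajectory), `best_fitness`, `report` (the
#'   held-out [full_report()]), `head` (the retrained `"softmax_head"`),
#'   `n_informative_selected` (when the input carries a ground-truth mask),
#'   `test_idx`, `config`, and `seed`.
#' @examples
#' fm <- gen_features(n = 120, d = 8, n_informative = 2, classes = 2,
#'                    delta = 2, seed = 7)
#' cfg <- fs_config(qga = qga_config(population_size = 8, max_generations = 5),
#'                  folds = 3, seed = 7)
#' sel <- qga_select(fm, cfg)
#' sel$selected
#' @export
qga_select <- function(fm, config = fs_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "fs_config"))
  if (fm$d < 2) stop("need at least 2 features to select from")

  set.seed(derive_seed(config$seed, 0L))
  test_idx <- stratified_holdout(fm$y, config$test_fraction)
  train <- subset_rows(fm, setdiff(seq_len(fm$n), test_idx))
  folds <- stratified_folds(train$y, config$folds)

  fitness <- function(bits) subset_fitness(train, bits, config, folds)
  qcfg <- config$qga
  qcfg$seed <- derive_seed(config$seed, 1L)
  run <- qga(fitness, fm$d, qcfg)

  mask <- as_mask(run$best_bits)
  if (!any(mask))
    stop("search degenerated to the empty mask; increase the budget or ",
         "check the data")

  hcfg <- config$head
  hcfg$seed <- derive_seed(config$seed, 2L)
  head <- train_head(apply_mask(train, mask), hcfg)

  test <- subset_rows(fm, test_idx)
  pred <- predict(head, apply_mask(test, mask))
  report <- full_report(test$y, pred, n_classes = fm$n_classes,
                        class_names = fm$class_names)

  structure(list(mask = mask, bits = as.integer(mask),
                 selected = fm$feature_names[mask],
                 n_selected = sum(mask),
                 run = run, best_fitness = run$best_fitness,
                 report = report, head = head,
                 n_informative_selected =
                   if (!is.null(fm$informative))
                     sum(mask & fm$informative) else NULL,
                 test_idx = test_idx,
                 config = config, seed = config$seed),
            class = "qgafs")
}

#' @export
print.qgafs <- function(x, ...) {
  cat("QGA feature selection\n")
  cat("  selected ", x$n_selected, " / ", length(x$mask), " features ",
      "(penalized CV fitness ", format(x$best_fitness, digits = 4), ")\n",
      sep = "")
  if (!is.null(x$n_informative_selected))
    cat("  known informative features recovered: ",
        x$n_informative_selected, "\n", sep = "")
  cat("  held-out accuracy ", format(x$report$accuracy, digits = 4),
      ", kappa ", format(x$report$kappa, digits = 4),
      ", MCC ", format(x$report$mcc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qgafs <- function(object, ...) {
  print(object)
  cat("\nSelected features:\n  ",
      paste(object$selected, collapse = ", "), "\n\nHeld-out ", sep = "")
  print(object$report)
  invisible(object)
}

#' @export
plot.qgafs <- function(x, ...) {
  plot(x$run, main = "QGA-FS fitness trajectory", ...)
}

#' Predict classes for new data from a selection result
#'
#' Applies the stored mask and the retrained head to new feature rows.
#'
#' @param object A `"qgafs"` object.
#' @param newdata A [feature_matrix()] or numeric matrix with the original
#'   `d` columns.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.qgafs <- function(object, newdata, type = c("class", "prob"), ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$x
       else as.matrix(newdata)
  if (ncol(X) != length(object$mask))
    stop("newdata has ", ncol(X), " features; expected ",
         length(object$mask))
  predict(object$head, X[, object$mask, drop = FALSE],
          type = match.arg(type))
}

#' @export
run_record.qgafs <- function(x, path = NULL, ...) {
  rec <- list(type = "qgafs",
              seed = x$seed,
              config = list(qga = unclass(x$config$qga),
                            classifier = x$config$classifier,
                            folds = x$config$folds,
                            lambda = x$config$lambda,
                            test_fraction = x$config$test_fraction),
              mask = x$bits,
              selected = x$selected,
              best_fitness = x$best_fitness,
              history = x$run$history,
              metrics = as.data.frame(x$report))
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
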