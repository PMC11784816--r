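#' Build a confusion matrix from label vectors
#'
#' Rows are true classes, columns predicted classes. Labels are integers in
#' `0..C-1` (factors are accepted and converted). Classes absent from both
#' vectors but below `n_classes` still get (empty) rows/columns.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param n_classes Number of classes `C`; defaults to `max(label) + 1`.
#' @return A `C x C` integer matrix with the class labels as dimnames.
#' @export
confusion_matrix <- function(truth, predicted, n_classes = NULL) {
  truth <- as_class_int(truth)
  predicted <- as_class_int(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have the same length")
  if (length(truth) == 0) stop("need at least one sample")
  if (is.null(n_classes)) n_classes <- max(truth, predicted) + 1L
  lev <- 0:(n_classes - 1L)
  cm <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = lev, predicted = lev))
  m
}

as_class_int <- function(x) {
  if (is.factor(x)) return(as.integer(x) - 1L)
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 0)) stop("labels must be non-negative integers")
  x
}

#' One-vs-rest counts for a single class
#'
#' Reduces a multiclass confusion matrix to the binary counts for class `class`:
#' `TP = cm[c,c]`, `FP` = rest of column `c`, `FN` = rest of row `c`,
#' `TN` = everything else.
#'
#' @param cm Square integer confusion matrix (rows true, columns predicted).
#' @param class Class label (0-based, matching the matrix dimnames) or, when
#'   the matrix has no dimnames, the 0-based index.
#' @return Named numeric vector `c(tp, fp, fn, tn)`.
#' @export
per_class_counts <- function(cm, class) {
  cm <- as.matrix(cm)
  labels <- rownames(cm)
  i <- if (!is.null(labels)) match(as.character(class), labels)
       else as.integer(class) + 1L
  if (is.na(i) || i < 1 || i > nrow(cm)) stop("unknown class: ", class)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Precision, recall and F1 from binary counts
#'
#' Precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = harmonic mean of the
#' two. Any zero denominator yields 0 (the degenerate-class convention, so
#' the metrics are total functions).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Overall accuracy
#'
#' Fraction of correctly classified samples: the trace of the confusion
#' matrix divided by its total (the one-vs-rest binary formula collapses to
#' this in the multiclass case).
#'
#' @param cm Square confusion matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p0 - pe) / (1 - pe)` where `p0` is
#' the observed agreement (trace/total) and `pe` the agreement expected from
#' the marginals, `sum(row_c * col_c) / total^2`. When `pe == 1` the ratio is
#' undefined: returns 1 for perfect agreement (`p0 == 1`) and 0 otherwise.
#'
#' @param cm Square confusion matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    return(if (p0 >= 1) 1 else 0)
  }
  (p0 - pe) / (1 - pe)
}

#' Matthews correlation coefficient
#'
#' For two classes, the classical formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. The default
#' multiclass form is the covariance generalization
#' `(n*trace - sum(t_k p_k)) / (sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2)))`
#' with `t_k`/`p_k` the true/predicted marginals, which reduces exactly to
#' the binary formula at `C = 2`. `type = "macro"` instead averages the
#' one-vs-rest binary MCC over classes. Zero denominators yield 0.
#'
#' @param cm Square confusion matrix.
#' @param type `"multiclass"` (default, covariance form) or `"macro"`
#'   (mean one-vs-rest binary MCC).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm, type = c("multiclass", "macro")) {
  type <- match.arg(type)
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  if (type == "macro") {
    vals <- vapply(seq_len(nrow(cm)), function(i) {
      ct <- per_class_counts(cm, rownames(cm)[i] %||% (i - 1L))
      binary_mcc(ct["tp"], ct["fp"], ct["fn"], ct["tn"])
    }, numeric(1))
    return(mean(vals))
  }
  tk <- rowSums(cm); pk <- colSums(cm)
  cov_xy <- n * sum(diag(cm)) - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) return(0)
  cov_xy / den
}

binary_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full multiclass evaluation report
#'
#' Builds the confusion matrix and computes per-class precision, recall and
#' F1, their macro averages, overall accuracy, Cohen's kappa and the Matthews
#' correlation coefficient — the full metric suite reported by the pipeline.
#'
#' @param truth,predicted Equal-length label vectors (integers `0..C-1` or
#'   factors).
#' @param n_classes Number of classes; defaults to the labels observed.
#' @param class_names Optional character vector of class names for printing.
#' @return An object of class `"metrics_report"`: list with `confusion`,
#'   `per_class` (data frame: class, precision, recall, f1, support),
#'   `accuracy`, `kappa`, `mcc`, `mcc_macro`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `n`.
#' @examples
#' truth <- c(0, 0, 1, 1, 2, 2)
#' pred  <- c(0, 0, 1, 2, 2, 2)
#' full_report(truth, pred)
#' @export
full_report <- function(truth, predicted, n_classes = NULL,
                        class_names = NULL) {
  cm <- confusion_matrix(truth, predicted, n_classes)
  C <- nrow(cm)
  prf <- t(vapply(seq_len(C), function(i) {
    ct <- per_class_counts(cm, rownames(cm)[i])
    precision_recall_f1(ct["tp"], ct["fp"], ct["fn"])
  }, numeric(3)))
  per_class <- data.frame(
    class = if (!is.null(class_names)) class_names else rownames(cm),
    precision = prf[, 1], recall = prf[, 2], f1 = prf[, 3],
    support = as.integer(rowSums(cm)), row.names = NULL)
  structure(list(confusion = cm,
                 per_class = per_class,
                 accuracy = accuracy(cm),
                 kappa = cohen_kappa(cm),
                 mcc = mcc(cm),
                 mcc_macro = mcc(cm, type = "macro"),
                 macro_precision = mean(prf[, 1]),
                 macro_recall = mean(prf[, 2]),
                 macro_f1 = mean(prf[, 3]),
                 n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Classification report (n = ", x$n, ")\n\n", sep = "")
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab, row.names = FALSE)
  cat("\n  Accuracy:      ", round(x$accuracy, digits), "\n")
  cat("  Cohen's kappa: ", round(x$kappa, digits), "\n")
  cat("  MCC:           ", round(x$mcc, digits), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, kappa = x$kappa, mcc = x$mcc,
             macro_precision = x$macro_precision,
             macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
             n = x$n)
}

# Delimited / JSON export used by the CLI.
write_report <- function(report, dir, prefix = "metrics") {
  utils::write.csv(report$per_class,
                   file.path(dir, paste0(prefix, "_per_class.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report),
                   file.path(dir, paste0(prefix, "_overall.csv")),
                   row.names = FALSE)
  utils::write.table(report$confusion,
                     file.path(dir, paste0(prefix, "_confusion.tsv")),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(report)
}
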