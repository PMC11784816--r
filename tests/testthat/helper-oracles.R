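# Independent textbook oracles and small generators shared across tests.

# Cohen's kappa straight from its definition, written against marginal
# probabilities (independent of the package's implementation path).
oracle_kappa <- function(cm) {
  n <- sum(cm)
  p0 <- sum(diag(cm)) / n
  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  (p0 - pe) / (1 - pe)
}

# Multiclass MCC as the Pearson correlation of one-hot indicator matrices:
# sum_k cov(T_k, P_k) / sqrt(sum_k var(T_k) * sum_k var(P_k)), computed from
# label vectors rather than confusion-matrix marginals.
oracle_mcc_onehot <- function(truth, pred, C) {
  Tm <- diag(C)[truth + 1L, , drop = FALSE]
  Pm <- diag(C)[pred + 1L, , drop = FALSE]
  num <- sum(vapply(1:C, function(k) cov(Tm[, k], Pm[, k]), numeric(1)))
  den <- sqrt(sum(vapply(1:C, function(k) cov(Tm[, k], Tm[, k]), numeric(1))) *
              sum(vapply(1:C, function(k) cov(Pm[, k], Pm[, k]), numeric(1))))
  num / den
}

# Label vectors realizing a given confusion matrix (rows true, cols pred).
labels_from_cm <- function(cm) {
  C <- nrow(cm)
  truth <- integer(); pred <- integer()
  for (i in 1:C) for (j in 1:C) {
    k <- cm[i, j]
    truth <- c(truth, rep(i - 1L, k)); pred <- c(pred, rep(j - 1L, k))
  }
  list(truth = truth, pred = pred)
}

random_confusion <- function(C, max_count = 12) {
  matrix(sample(0:max_count, C * C, replace = TRUE), C, C,
         dimnames = list(true = 0:(C - 1), predicted = 0:(C - 1)))
}

# All non-empty bit masks of length d, one per row.
all_masks <- function(d) {
  as.matrix(expand.grid(rep(list(0:1), d)))[-1, , drop = FALSE]
}

# Exhaustive-search optimum of a fitness function over bitstrings.
exhaustive_optimum <- function(fitness, m) {
  max(apply(all_masks(m), 1, fitness), fitness(rep(0L, m)))
}

# Build a register with prescribed bit-1 probabilities (for observe tests).
register_with_p1 <- function(p1) {
  reg <- qubit_register(length(p1), 1)
  reg$beta <- matrix(sqrt(p1), length(p1), 1)
  reg$alpha <- matrix(sqrt(1 - p1), length(p1), 1)
  reg
}

# Held-out accuracy of an LDA probe on selected columns (generator oracle).
probe_accuracy <- function(fm, cols, seed = 1) {
  set.seed(seed)
  test <- qgafs:::stratified_holdout(fm$y, 0.25)
  tr <- setdiff(seq_len(fm$n), test)
  x <- fm$x[, cols, drop = FALSE]
  x <- x[, apply(x[tr, , drop = FALSE], 2, sd) > 1e-10, drop = FALSE]
  fit <- suppressWarnings(MASS::lda(x[tr, , drop = FALSE],
                                    grouping = factor(fm$y[tr])))
  pred <- as.integer(as.character(predict(fit, x[test, , drop = FALSE])$class))
  mean(pred == fm$y[test])
}
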