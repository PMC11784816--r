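make_fixture_tree <- function(root, classes = c("a", "b"), n = 3,
                              size = 32) {
  set.seed(1)
  for (ci in seq_along(classes)) {
    d <- file.path(root, classes[ci])
    dir.create(d, recursive = TRUE)
    for (i in seq_len(n)) {
      img <- matrix(runif(size * size, 0, ci / length(classes)), size, size)
      png::writePNG(img, file.path(d, sprintf("img%02d.png", i)))
    }
  }
  root
}

test_that("directory loading orders classes lexicographically", {
  root <- withr::local_tempdir()
  make_fixture_tree(root, c("b", "a"), n = 3)
  ds <- load_image_dir(root, size = 32)
  expect_equal(ds$n, 6)
  expect_equal(ds$class_names, c("a", "b"))
  expect_equal(ds$labels, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(vapply(ds$images, function(im)
    identical(dim(im), c(32L, 32L, 3L)), logical(1))))
})

test_that("unreadable files are skipped with a warning; empty inputs error", {
  root <- withr::local_tempdir()
  make_fixture_tree(root, c("a", "b"), n = 3)
  writeLines("not a png", file.path(root, "a", "junk.png"))
  expect_warning(ds <- load_image_dir(root, size = 32), "unreadable")
  expect_equal(ds$n, 6)
  expect_equal(ds$n_skipped, 1L)

  empty <- withr::local_tempdir()
  expect_error(load_image_dir(empty), "empty root")
  dir.create(file.path(empty, "c"))
  writeLines("nope", file.path(empty, "c", "bad.png"))
  expect_error(suppressWarnings(load_image_dir(empty)),
               "no readable images")
})

test_that("preprocessing normalizes, resizes, replicates channels, idempotent", {
  gray <- matrix(255L, 256, 256)
  storage.mode(gray) <- "integer"
  out <- preprocess_image(gray)
  expect_equal(dim(out), c(128L, 128L, 3L))
  expect_true(all(out == 1))

  conforming <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_equal(preprocess_image(conforming), conforming)
  expect_equal(preprocess_image(preprocess_image(conforming)),
               preprocess_image(conforming))

  # bilinear resampling of a linear gradient stays (nearly) that gradient
  grad <- matrix(seq(0, 1, length.out = 100), 100, 90)
  out <- preprocess_image(grad)
  expect_equal(dim(out), c(128L, 128L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  expected <- seq(0, 1, length.out = 128)
  expect_lt(max(abs(out[, 64, 1] - expected)), 0.05)
  expect_lt(max(abs(out[, 5, 1] - out[, 120, 1])), 1e-12)

  expect_error(preprocess_image(array(0, c(4, 4, 4, 4))), "non-image")
  expect_error(preprocess_image(array(0, c(8, 8, 2))), "non-image")
  expect_error(preprocess_image("x"), "numeric")
})

test_that("feature extraction is deterministic, sensitive and order-equivariant", {
  ext <- random_projection_extractor(d = 12, size = 32, seed = 4)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  img2 <- img; img2[5, 5, 1] <- img2[5, 5, 1] + 0.5
  ds <- structure(list(images = list(img, img, img2, img2),
                       labels = c(0L, 0L, 1L, 1L),
                       class_names = c("a", "b"), paths = letters[1:4],
                       n = 4L, n_classes = 2L, n_skipped = 0L),
                  class = "image_dataset")
  fm <- extract_features(ds, ext)
  expect_equal(fm$x[1, ], fm$x[2, ])                 # identical images
  expect_false(isTRUE(all.equal(fm$x[1, ], fm$x[3, ])))  # one-pixel change

  # permuting rows permutes the matrix identically
  imgs <- lapply(1:6, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  ds3 <- structure(list(images = imgs, labels = rep(0:1, each = 3),
                        class_names = c("a", "b"), paths = letters[1:6],
                        n = 6L, n_classes = 2L, n_skipped = 0L),
                   class = "image_dataset")
  perm <- c(4, 1, 6, 2, 5, 3)
  ds3p <- ds3; ds3p$images <- imgs[perm]; ds3p$labels <- ds3$labels[perm]
  expect_equal(extract_features(ds3p, ext)$x,
               extract_features(ds3, ext)$x[perm, ], ignore_attr = TRUE)

  ds0 <- ds3
  ds0$images <- list(); ds0$n <- 0L; ds0$labels <- integer()
  expect_error(extract_features(ds0, ext), "empty dataset")

  bad <- ext; bad$d <- 99L
  expect_error(extract_features(ds3, bad), "contract violation")
})

test_that("head training separates separable classes and respects callbacks", {
  fm <- gen_features(n = 360, d = 16, n_informative = 9, classes = 3,
                     delta = 3, seed = 31)
  tr <- seq_len(300); te <- 301:360
  head <- train_head(qgafs:::subset_rows(fm, tr),
                     head_config(seed = 1, max_epochs = 40))
  acc <- mean(predict(head, fm$x[te, , drop = FALSE]) == fm$y[te])
  expect_gte(acc, 0.95)
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in%
                    names(head$history)))
  # early stopping: training never runs past best epoch + patience
  best_epoch <- which.min(head$history$val_loss)
  expect_lte(nrow(head$history), best_epoch + head$config$patience)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  fm <- gen_features(n = 300, d = 12, n_informative = 6, classes = 3,
                     delta = 3, seed = 13)
  set.seed(7)
  y_shuf <- sample(fm$y)
  fm_null <- feature_matrix(fm$x, y_shuf)
  tr <- seq_len(240); te <- 241:300
  head <- train_head(qgafs:::subset_rows(fm_null, tr),
                     head_config(seed = 2, max_epochs = 20))
  acc <- mean(predict(head, fm_null$x[te, , drop = FALSE]) == fm_null$y[te])
  expect_gte(acc, 1 / 3 - 0.15)
  expect_lte(acc, 1 / 3 + 0.15)
})

test_that("head training is deterministic under a fixed seed", {
  fm <- gen_features(n = 150, d = 8, n_informative = 4, classes = 3,
                     delta = 2, seed = 3)
  cfg0 <- head_config(seed = 5, dropout = 0, max_epochs = 8)
  h1 <- train_head(fm, cfg0)
  h2 <- train_head(fm, cfg0)
  expect_identical(h1$W1, h2$W1)
  expect_identical(h1$history, h2$history)
  cfg_d <- head_config(seed = 5, dropout = 0.5, max_epochs = 8)
  expect_identical(train_head(fm, cfg_d)$history,
                   train_head(fm, cfg_d)$history)
  expect_error(train_head(qgafs:::subset_rows(fm, which(fm$y == 0)),
                          cfg0))
})
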