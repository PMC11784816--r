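#' Generate a class-conditional Gaussian feature matrix
#'
#' Emulates the post-extraction representation the selection stage works on:
#' `n` samples by `d` features with integer class labels, of which
#' `n_informative` columns carry class signal and the rest are pure noise.
#' Each informative column `j` is assigned one class (round-robin over the
#' `classes` labels) whose mean on that column is shifted by `delta * sigma`;
#' all other entries are `N(0, sigma^2)` noise. Each informative feature is
#' therefore a noisy one-vs-rest indicator of its class, individually weak
#' but jointly separating the classes — the regime in which wrapper feature
#' selection has a well-defined ground truth. `delta = 0` is the null
#' generator (no signal anywhere).
#'
#' Class labels are balanced to within one sample. Informative columns are
#' placed at random positions and recorded in the `informative` mask.
#' Deterministic given `seed`.
#'
#' @param n Number of samples (at least `10 * classes`).
#' @param d Number of features.
#' @param n_informative Number of informative columns, `1 <= k <= d`.
#' @param classes Number of classes `C >= 2`.
#' @param delta Class-mean separation in units of `sigma` (`>= 0`).
#' @param sigma Noise standard deviation (`> 0`).
#' @param seed Integer seed.
#' @return A [feature_matrix()] with the ground-truth `informative` mask.
#' @export
gen_features <- function(n = 600, d = 64, n_informative = 8, classes = 3,
                         delta = 2, sigma = 1, seed = 1) {
  if (classes < 2) stop("`classes` must be >= 2")
  if (n_informative < 1 || n_informative > d)
    stop("`n_informative` must be in 1..d")
  if (delta < 0) stop("`delta` must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (n < 10 * classes) stop("`n` must be at least 10 * classes")
  set.seed(seed)

  y <- sample(rep(0:(classes - 1L), length.out = n))
  x <- matrix(stats::rnorm(n * d, sd = sigma), n, d)

  info_cols <- sort(sample.int(d, n_informative))
  assigned <- rep(0:(classes - 1L), length.out = n_informative)
  for (j in seq_len(n_informative)) {
    rows <- y == assigned[j]
    x[rows, info_cols[j]] <- x[rows, info_cols[j]] + delta * sigma
  }

  informative <- rep(FALSE, d)
  informative[info_cols] <- TRUE
  feature_matrix(x, y,
                 feature_names = sprintf("f%03d", seq_len(d) - 1L),
                 informative = informative)
}

# Geometric motifs drawn on a [0,1] grayscale canvas; coordinates in [0,1].
motif_canvas <- function(motif, size, fg) {
  g <- seq(0, 1, length.out = size)
  xx <- matrix(g, size, size)
  yy <- matrix(g, size, size, byrow = TRUE)
  r <- sqrt((xx - 0.5)^2 + (yy - 0.5)^2)
  img <- matrix(0.08, size, size)
  mask <- switch(motif,
    disc  = r < 0.28,
    ring  = r > 0.2 & r < 0.33,
    cross = (abs(xx - 0.5) < 0.08 | abs(yy - 0.5) < 0.08) & r < 0.42,
    blank = matrix(FALSE, size, size),
    stop("unknown motif '", motif, "'"))
  img[mask] <- fg
  img
}

#' Generate a class-labeled directory of motif images
#'
#' Writes PNG images in one subdirectory per class, the layout consumed by
#' [load_image_dir()]. Classes are distinct geometric motifs (disc, ring,
#' cross, blank) drawn at a fixed position with per-image intensity jitter
#' and additive pixel noise, so classes are linearly separable from raw
#' pixels (until `noise` drowns the signal). Deterministic given `seed`:
#' identical calls produce byte-identical files.
#'
#' @param out_dir Output directory (created; must not already contain class
#'   subdirectories unless `force = TRUE`).
#' @param n_per_class Images per class.
#' @param classes Number of classes (2..4), or a character vector of motif
#'   names from `c("disc", "ring", "cross", "blank")`.
#' @param size Image side length in pixels (>= 32).
#' @param noise Standard deviation of additive Gaussian pixel noise
#'   (images are clipped back to `[0, 1]`). `noise >= 1` effectively erases
#'   the motif signal.
#' @param seed Integer seed.
#' @param force Overwrite existing class subdirectories.
#' @return `out_dir`, invisibly.
#' @export
gen_images <- function(out_dir, n_per_class = 20, classes = 3, size = 64,
                       noise = 0.05, seed = 1, force = FALSE) {
  motifs <- c("disc", "ring", "cross", "blank")
  if (is.character(classes)) {
    bad <- setdiff(classes, motifs)
    if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "))
    motifs <- classes
  } else {
    if (classes < 2 || classes > 4) stop("`classes` must be in 2..4")
    motifs <- motifs[seq_len(classes)]
  }
  if (size < 32) stop("`size` must be >= 32")
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  for (m in motifs) {
    cls_dir <- file.path(out_dir, m)
    if (dir.exists(cls_dir) && !force)
      stop("class directory exists: ", cls_dir, " (use force = TRUE)")
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      fg <- stats::runif(1, 0.7, 1)
      img <- motif_canvas(m, size, fg)
      if (noise > 0)
        img <- img + matrix(stats::rnorm(size * size, sd = noise), size, size)
      img[img < 0] <- 0; img[img > 1] <- 1
      png::writePNG(img, file.path(cls_dir, sprintf("%s_%03d.png", m, i)))
    }
  }
  invisible(out_dir)
}
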