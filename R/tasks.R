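new_labeled_dataset <- function(x, y, x_test, y_test, n_classes, provenance) {
  structure(list(x = x, y = y, x_test = x_test, y_test = y_test,
                 n_classes = n_classes, provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n_tr <- if (is.matrix(x$x)) ncol(x$x) else dim(x$x)[length(dim(x$x))]
  n_te <- if (is.null(x$x_test)) 0 else if (is.matrix(x$x_test)) ncol(x$x_test)
          else dim(x$x_test)[length(dim(x$x_test))]
  cat(sprintf("<labeled_dataset: %d train / %d test, %d classes, %s>\n",
              n_tr, n_te, x$n_classes, x$provenance$source))
  invisible(x)
}

#' Synthetic classification task from a random teacher network
#'
#' Draws i.i.d. standard-Gaussian inputs and labels them with the argmax of
#' a fixed random teacher network's output: a linear map for
#' `teacher_depth = 1`, otherwise an MLP with tanh hidden layers. A fraction
#' `noise_rate` of labels is resampled uniformly. The task is exactly
#' reproducible from its arguments and seed; inputs are standard Gaussian,
#' hence already standardized.
#'
#' @param input_dim Input dimensionality.
#' @param n_classes Number of classes (>= 2).
#' @param n_samples Training-set size.
#' @param teacher_depth Number of teacher weight layers (1 = linear teacher).
#' @param noise_rate Fraction of labels replaced by uniform draws.
#' @param seed Integer seed.
#' @param n_test Held-out test-set size drawn from the same teacher.
#' @return A `labeled_dataset` with `x` (`input_dim x n_samples`), integer
#'   labels `y` in `1..n_classes`, and matching `x_test`/`y_test`.
#' @export
gen_teacher_task <- function(input_dim, n_classes, n_samples,
                             teacher_depth = 1, noise_rate = 0, seed = 1,
                             n_test = 0) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  stopifnot(noise_rate >= 0, noise_rate <= 1, teacher_depth >= 1)
  set.seed(seed)
  hidden <- max(2 * input_dim, 16)
  sizes <- c(input_dim, rep(hidden, teacher_depth - 1), n_classes)
  teacher <- lapply(seq_len(length(sizes) - 1), function(l) {
    matrix(stats::rnorm(sizes[l + 1] * sizes[l], sd = 1 / sqrt(sizes[l])),
           sizes[l + 1], sizes[l])
  })
  label_batch <- function(x) {
    h <- x
    for (l in seq_along(teacher)) {
      h <- teacher[[l]] %*% h
      if (l < length(teacher)) h <- tanh(h)
    }
    y <- max.col(t(h), ties.method = "first")
    flip <- stats::runif(ncol(x)) < noise_rate
    y[flip] <- sample.int(n_classes, sum(flip), replace = TRUE)
    y
  }
  x <- matrix(stats::rnorm(input_dim * n_samples), input_dim, n_samples)
  y <- label_batch(x)
  x_test <- NULL; y_test <- NULL
  if (n_test > 0) {
    x_test <- matrix(stats::rnorm(input_dim * n_test), input_dim, n_test)
    y_test <- label_batch(x_test)
  }
  new_labeled_dataset(x, y, x_test, y_test, n_classes,
                      list(source = "synthetic_teacher", seed = seed,
                           input_dim = input_dim, teacher_depth = teacher_depth,
                           noise_rate = noise_rate))
}

#' Synthetic image-classification task from a random conv teacher
#'
#' Small standard-Gaussian images labeled by the argmax of a fixed random
#' teacher consisting of one 3x3 convolution (ReLU) followed by a linear
#' readout of the flattened maps. Images whose top-two teacher logits differ
#' by less than `margin` are rejected and redrawn, so every kept label has a
#' definite margin (without this, images that silence every ReLU feature get
#' tied zero logits and arbitrary labels, putting a hard ceiling on any
#' learner's accuracy). Deterministic given the seed.
#'
#' @param image_size Side length of the square images.
#' @param n_channels Input channels.
#' @param n_classes Number of classes (>= 2).
#' @param n_samples Training-set size.
#' @param seed Integer seed.
#' @param n_test Held-out test-set size.
#' @param margin Minimum top-two teacher logit gap (same scale as the
#'   teacher's unit-variance logits).
#' @return A `labeled_dataset` with `x` an `(image_size, image_size,
#'   n_channels, n_samples)` array.
#' @export
gen_conv_task <- function(image_size = 8, n_channels = 1, n_classes = 2,
                          n_samples = 500, seed = 1, n_test = 0,
                          margin = 0.2) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  stopifnot(margin >= 0)
  set.seed(seed)
  t_out <- 4L
  K <- array(stats::rnorm(3 * 3 * n_channels * t_out,
                          sd = 1 / sqrt(9 * n_channels)),
             dim = c(3, 3, n_channels, t_out))
  o <- image_size - 2
  Wro <- matrix(stats::rnorm(n_classes * o * o * t_out,
                             sd = 1 / sqrt(o * o * t_out)),
                n_classes, o * o * t_out)
  teacher_logits <- function(x) {
    ic <- im2col(x, 3, 3, stride = 1, padding = 0, dilation = 1)
    Z <- crossprod(matrix(K, 9 * n_channels, t_out), ic$Xcol)
    h <- pmax(cols_to_maps(Z, ic$oh, ic$ow, dim(x)[4]), 0)
    Wro %*% matrix(h, o * o * t_out, dim(x)[4])
  }
  draw_labeled <- function(n) {
    xs <- NULL; ys <- integer(0)
    while (length(ys) < n) {
      cand <- array(stats::rnorm(image_size^2 * n_channels * 2 * n),
                    dim = c(image_size, image_size, n_channels, 2 * n))
      lg <- teacher_logits(cand)
      srt <- apply(lg, 2, function(v) diff(sort(v, decreasing = TRUE)[2:1]))
      keep <- which(srt >= margin)
      if (length(keep)) {
        xs <- if (is.null(xs)) cand[, , , keep, drop = FALSE] else {
          ab <- array(0, dim = c(image_size, image_size, n_channels,
                                 dim(xs)[4] + length(keep)))
          ab[, , , seq_len(dim(xs)[4])] <- xs
          ab[, , , dim(xs)[4] + seq_along(keep)] <- cand[, , , keep]
          ab
        }
        ys <- c(ys, max.col(t(lg[, keep, drop = FALSE]), ties.method = "first"))
      }
    }
    list(x = xs[, , , seq_len(n), drop = FALSE], y = ys[seq_len(n)])
  }
  tr <- draw_labeled(n_samples)
  x <- tr$x; y <- tr$y
  x_test <- NULL; y_test <- NULL
  if (n_test > 0) { te <- draw_labeled(n_test); x_test <- te$x; y_test <- te$y }
  new_labeled_dataset(x, y, x_test, y_test, n_classes,
                      list(source = "synthetic_conv_teacher", seed = seed,
                           image_size = image_size, n_channels = n_channels))
}

#' Read an MNIST-style IDX dataset
#'
#' Parses the classic IDX binary pair (`idx3-ubyte` images, magic
#' `0x00000803`; `idx1-ubyte` labels, magic `0x00000801`) with big-endian
#' dimension headers; files may be gzip-compressed. Pixels are scaled to
#' `[0, 1]` and images flattened to columns of length `rows * cols` (784 for
#' MNIST); labels are shifted to `1..n_classes`. The package never downloads
#' data; pass local file paths.
#'
#' @param images_path,labels_path Paths to the image and label files
#'   (optionally `.gz`).
#' @return A `labeled_dataset` (all data in the train slot; split as you see
#'   fit).
#' @export
read_mnist_idx <- function(images_path, labels_path) {
  img <- read_idx_file(images_path, expect_magic = 2051L, ndim = 3L)
  lab <- read_idx_file(labels_path, expect_magic = 2049L, ndim = 1L)
  n <- img$dims[1]
  if (lab$dims[1] != n) {
    stop(sprintf("label count (%d) does not match image count (%d)",
                 lab$dims[1], n), call. = FALSE)
  }
  px <- img$dims[2] * img$dims[3]
  # payload order: image-major, row-major within an image
  x <- matrix(img$data / 255, nrow = px, ncol = n)
  y <- as.integer(lab$data) + 1L
  new_labeled_dataset(x, y, NULL, NULL, n_classes = max(y),
                      list(source = "mnist_idx", images = images_path,
                           labels = labels_path))
}

read_idx_file <- function(path, expect_magic, ndim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")   # reads plain files too
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(magic) == 0 || magic != expect_magic) {
    stop(sprintf("IDX magic mismatch at byte 0 in %s: expected %d, got %s",
                 path, expect_magic,
                 if (length(magic)) magic else "EOF"), call. = FALSE)
  }
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  if (length(dims) != ndim || any(dims < 0)) {
    stop(sprintf("truncated IDX header in %s at byte %d", path,
                 4 + 4 * length(dims)), call. = FALSE)
  }
  total <- prod(dims)
  data <- readBin(con, "integer", n = total, size = 1, signed = FALSE)
  if (length(data) != total) {
    stop(sprintf("truncated IDX payload in %s: expected %d bytes, got %d (offset %d)",
                 path, total, length(data), 4 + 4 * ndim + length(data)),
         call. = FALSE)
  }
  list(dims = dims, data = data)
}
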