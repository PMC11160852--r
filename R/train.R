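#' Train a network with a chosen credit-assignment rule
#'
#' The main harness: runs minibatch SGD with the configured backward rule,
#' the two-phase weight-decay schedule, and fixed sparsity masks, recording
#' the training loss per epoch, the test accuracy (forward pass only), and
#' the per-layer alignment diagnostics at every epoch end.
#'
#' Randomness is fully determined by `config$seed` through named substreams
#' (network init / feedback init / data order), so a `(config, data)` pair
#' reproduces a run bit-for-bit.
#'
#' @param data A `labeled_dataset` (matrix `x` for dense networks, a
#'   4-d array for conv networks; `x_test`/`y_test` optional).
#' @param config A [train_config()].
#' @param net Optional pre-built `pfa_network`; by default an MLP
#'   `input_dim - hidden... - n_classes` is built from `config$hidden`.
#' @param feedback Optional pre-built `pfa_feedback` matching `net`.
#' @return An object of class `pfa_fit`: list with `net`, `feedback`,
#'   `history` (tibble: epoch, train_loss, test_accuracy), `metrics`
#'   (tibble: epoch, layer, algorithm, angle_deg, norm_ratio), `config`.
#' @export
train_network <- function(data, config, net = NULL, feedback = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "train_config"))
  if (is.null(net)) {
    if (!is.matrix(data$x)) {
      stop("pass a pre-built conv network via `net` for image data", call. = FALSE)
    }
    set.seed(substream_seed(config$seed, "init"))
    net <- mlp_network(c(nrow(data$x), config$hidden, data$n_classes),
                       activation = config$activation)
  }
  if (is.null(feedback)) {
    feedback <- init_feedback(net, config$algorithm,
                              expansion_ratio = config$expansion_ratio,
                              sparsity = config$sparsity,
                              seed = substream_seed(config$seed, "feedback"),
                              r_init = config$r_init)
  }
  n <- if (is.matrix(data$x)) ncol(data$x) else dim(data$x)[length(dim(data$x))]
  set.seed(substream_seed(config$seed, "data"))

  history <- vector("list", config$epochs)
  metrics <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    gamma <- if (epoch <= config$wd_switch_epoch) config$wd_initial else config$wd_main
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
      xb <- take_samples(data$x, idx)
      fwd <- forward(net, xb)
      net <- fwd$net
      oe <- output_error(fwd$output, data$y[idx])
      if (!is.finite(oe$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d; last good epoch %d",
                     epoch, bi, epoch - 1L), call. = FALSE)
      }
      losses[bi] <- oe$loss
      bwd <- backward(net, feedback, oe$e)
      feedback <- bwd$feedback
      step <- sgd_step(net, feedback, bwd$errors,
                       eta_w = config$lr, eta_r = config$lr_r,
                       gamma_w = gamma, gamma_r = gamma)
      net <- step$net
      feedback <- step$feedback
    }
    acc <- if (!is.null(data$x_test)) {
      evaluate_accuracy(net, data$x_test, data$y_test, config$batch_size)
    } else NA_real_
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(losses),
                                       test_accuracy = acc)
    m <- network_alignment(net, feedback)
    if (nrow(m)) m$epoch <- epoch
    metrics[[epoch]] <- m
  }
  structure(list(net = net, feedback = feedback,
                 history = dplyr::bind_rows(history),
                 metrics = dplyr::bind_rows(metrics),
                 config = config),
            class = "pfa_fit")
}

take_samples <- function(x, idx) {
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[, , , idx, drop = FALSE]
}

#' Classification accuracy of a trained network
#'
#' Forward pass only; feedback structures are not touched.
#'
#' @param net A `pfa_network`.
#' @param x,y Inputs and integer labels.
#' @param batch_size Evaluation batch size.
#' @return Fraction of correct argmax predictions.
#' @export
evaluate_accuracy <- function(net, x, y, batch_size = 256) {
  n <- if (is.matrix(x)) ncol(x) else dim(x)[length(dim(x))]
  correct <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    out <- forward(net, take_samples(x, idx))$output
    correct <- correct + sum(max.col(t(out)) == y[idx])
  }
  correct / n
}

#' @export
print.pfa_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<pfa_fit %s: %d epochs, final train loss %.4f, test accuracy %s>\n",
              x$config$algorithm, nrow(x$history), h$train_loss,
              if (is.na(h$test_accuracy)) "NA" else sprintf("%.3f", h$test_accuracy)))
  invisible(x)
}

#' Tidy methods for fitted runs
#'
#' `tidy()` returns the per-epoch, per-layer alignment diagnostics joined
#' with the loss/accuracy history; `glance()` a one-row summary of the final
#' epoch.
#'
#' @param x,object A `pfa_fit`.
#' @param ... Unused.
#' @export
tidy.pfa_fit <- function(x, ...) {
  if (nrow(x$metrics) == 0) return(x$history)
  dplyr::left_join(x$metrics, x$history, by = "epoch")
}

#' @rdname tidy.pfa_fit
#' @export
glance.pfa_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  m <- x$metrics
  last <- if (nrow(m)) m[m$epoch == max(m$epoch), ] else m
  tibble::tibble(algorithm = x$config$algorithm,
                 epochs = nrow(x$history),
                 final_train_loss = h$train_loss,
                 final_test_accuracy = h$test_accuracy,
                 mean_angle_deg = if (nrow(last)) mean(last$angle_deg) else NA_real_,
                 mean_norm_ratio = if (nrow(last)) mean(last$norm_ratio) else NA_real_,
                 seed = x$config$seed)
}

#' @rdname tidy.pfa_fit
#' @export
autoplot.pfa_fit <- function(object, ...) {
  df <- tidy(object)
  if (!"layer" %in% names(df)) {
    return(ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$train_loss)) +
             ggplot2::geom_line() + ggplot2::theme_minimal() +
             ggplot2::labs(y = "training loss"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$angle_deg,
                                   colour = factor(.data$layer))) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "alignment angle (deg)", colour = "layer",
                  title = sprintf("Backward-forward alignment (%s)",
                                  object$config$algorithm)) +
    ggplot2::theme_minimal()
}

#' Sparsity sweep over feedback density
#'
#' Trains one run per (algorithm, sparsity level, seed) with feedback masks
#' of density `1 - p` and collects the final test accuracy: the desk-scale
#' analogue of sweeping feedback sparsity. At `p = 0` the run is identical
#' to an unsparsified run with the same seed.
#'
#' @param data A `labeled_dataset` with a test split.
#' @param config Base [train_config()] (its `algorithm`, `sparsity` and
#'   `seed` are overridden per run).
#' @param sparsity_levels Numeric vector of `p` values in `[0, 1)`.
#' @param algorithms Character vector of algorithm tags.
#' @param seeds Integer vector of seeds.
#' @return A tibble: `algorithm`, `sparsity`, `seed`, `final_accuracy`,
#'   `final_loss`.
#' @export
run_sparsity_sweep <- function(data, config, sparsity_levels = c(0, 0.5, 0.9),
                               algorithms = c("fa", "pfa"), seeds = 1:5) {
  rows <- list()
  for (alg in algorithms) {
    for (p in sparsity_levels) {
      for (s in seeds) {
        cfg <- config
        cfg$algorithm <- match.arg(alg, .algorithms)
        cfg$sparsity <- p
        cfg$seed <- as.integer(s)
        fit <- train_network(data, cfg)
        g <- glance(fit)
        rows[[length(rows) + 1]] <- tibble::tibble(
          algorithm = alg, sparsity = p, seed = s,
          final_accuracy = g$final_test_accuracy,
          final_loss = g$final_train_loss)
      }
    }
  }
  dplyr::bind_rows(rows)
}
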