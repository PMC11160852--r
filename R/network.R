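#' Multilayer network
#'
#' Bundles an ordered list of layers into a network. Adjacent dense layer
#' sizes must chain (layer l maps N_l inputs to N_{l+1} outputs); conv layer
#' channel counts must chain likewise, with an optional [flatten_layer()]
#' between the convolutional stack and the dense head.
#'
#' @param layers List of layers built with [dense_layer()], [conv_layer()]
#'   and [flatten_layer()].
#' @return An object of class `pfa_network`.
#' @export
network <- function(layers) {
  stopifnot(length(layers) >= 1)
  prev <- NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!inherits(l, "pfa_layer")) stop("layer ", i, " is not a pfa_layer")
    if (!is.null(prev)) {
      if (l$type == "dense" && prev$type == "dense" && l$n_in != prev$n_out) {
        stop(sprintf("layer %d expects %d inputs but layer %d produces %d",
                     i, l$n_in, i - 1, prev$n_out), call. = FALSE)
      }
      if (l$type == "conv" && prev$type == "conv" &&
          l$in_channels != prev$out_channels) {
        stop(sprintf("layer %d expects %d channels but layer %d produces %d",
                     i, l$in_channels, i - 1, prev$out_channels), call. = FALSE)
      }
    }
    prev <- l
  }
  structure(list(layers = layers), class = "pfa_network")
}

#' Fully connected network from a size vector
#'
#' Convenience constructor for the common multilayer perceptron: hidden
#' layers use `activation`, the output layer is linear (logits feed the
#' softmax cross-entropy in [output_error()]).
#'
#' @param sizes Integer vector of layer sizes `N_0, ..., N_L` (length >= 2).
#' @param activation Hidden-layer activation.
#' @param seed Optional integer seed for the weight initialization.
#' @return A `pfa_network`.
#' @export
mlp_network <- function(sizes, activation = "relu", seed = NULL) {
  stopifnot(length(sizes) >= 2)
  if (!is.null(seed)) set.seed(seed)
  L <- length(sizes) - 1
  layers <- lapply(seq_len(L), function(l) {
    dense_layer(sizes[l], sizes[l + 1],
                activation = if (l == L) "identity" else activation)
  })
  network(layers)
}

#' @export
print.pfa_network <- function(x, ...) {
  cat("<pfa_network with", length(x$layers), "layers>\n")
  for (l in x$layers) print(l)
  invisible(x)
}

# ---- forward pass -----------------------------------------------------------

forward_layer <- function(layer, x) UseMethod("forward_layer")

#' @export
forward_layer.dense_layer <- function(layer, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != layer$n_in) {
    stop(sprintf("dense layer expects %d inputs, got %d", layer$n_in, nrow(x)),
         call. = FALSE)
  }
  z <- layer$W %*% x + layer$b
  a <- act_fun(layer$activation)(z)
  layer$cache <- list(input = x, pre = z)
  list(layer = layer, out = a)
}

#' @export
forward_layer.flatten_layer <- function(layer, x) {
  d <- dim(x)
  if (length(d) != 4) stop("flatten expects (h, w, c, batch) input", call. = FALSE)
  layer$cache <- list(in_dim = d)
  list(layer = layer, out = matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Forward pass
#'
#' Runs the network on a batch of inputs, caching every layer's input and
#' preactivation for a subsequent backward pass. Dense inputs are a matrix
#' with one column per sample (a plain vector is treated as one sample);
#' convolutional inputs are (height, width, channel, batch) arrays.
#'
#' @param net A `pfa_network`.
#' @param x Input batch.
#' @return A list with the updated network (`net`, caches populated) and the
#'   output activations (`output`).
#' @export
forward <- function(net, x) {
  stopifnot(inherits(net, "pfa_network"))
  for (i in seq_along(net$layers)) {
    res <- tryCatch(forward_layer(net$layers[[i]], x),
                    error = function(e) {
                      stop("forward failed at layer ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    net$layers[[i]] <- res$layer
    x <- res$out
  }
  list(net = net, output = x)
}

# ---- output error -----------------------------------------------------------

#' Softmax cross-entropy loss and output error
#'
#' Computes the mean softmax cross-entropy over the batch and the output
#' teaching signal `e_L = -dL/dx_L` per sample, i.e. one-hot(target) minus
#' the softmax probabilities. The sign convention makes every weight update
#' additive (`W <- W + eta * e x'`).
#'
#' @param logits Output activations, `n_classes x batch` matrix (or vector
#'   for a single sample).
#' @param targets Integer class labels in `1..n_classes`.
#' @return A list with `loss` (scalar, mean over the batch), `e` (the
#'   per-sample output error matrix, `n_classes x batch`), and `probs`.
#' @export
output_error <- function(logits, targets) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1)
  n_classes <- nrow(logits)
  n <- ncol(logits)
  targets <- as.integer(targets)
  if (length(targets) != n) stop("length(targets) must equal ncol(logits)", call. = FALSE)
  if (any(targets < 1L | targets > n_classes)) {
    stop("targets must lie in 1..", n_classes, call. = FALSE)
  }
  z <- sweep(logits, 2, apply(logits, 2, max))   # stabilized softmax
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(targets, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  e <- -p
  e[idx] <- e[idx] + 1
  list(loss = loss, e = e, probs = p)
}
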