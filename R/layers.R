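#' Dense (fully connected) layer
#'
#' Constructs the state of one fully connected layer mapping `n_in` inputs to
#' `n_out` outputs: a weight matrix `W` (rows index output units), a bias
#' vector `b`, and an activation. Weights are initialized i.i.d. Gaussian with
#' standard deviation `1/sqrt(n_in)`; biases start at zero. The forward pass
#' caches the layer input and preactivation so that backward rules can
#' evaluate the activation derivative where the forward pass did.
#'
#' @param n_in,n_out Number of input and output units.
#' @param activation One of `"relu"`, `"identity"`, `"tanh"`.
#' @param init_sd Standard deviation of the Gaussian weight initialization;
#'   defaults to `1/sqrt(n_in)`.
#' @return An object of class `dense_layer`.
#' @export
dense_layer <- function(n_in, n_out, activation = "relu", init_sd = NULL) {
  check_activation(activation)
  stopifnot(n_in >= 1, n_out >= 1)
  init_sd <- init_sd %||% (1 / sqrt(n_in))
  W <- matrix(stats::rnorm(n_out * n_in, sd = init_sd), n_out, n_in)
  structure(
    list(
      type = "dense", W = W, b = numeric(n_out),
      n_in = n_in, n_out = n_out, activation = activation,
      cache = NULL
    ),
    class = c("dense_layer", "pfa_layer")
  )
}

#' Convolutional layer
#'
#' Constructs a 2-d convolutional layer. The kernel is stored with axes
#' (kernel height, kernel width, in-channels, out-channels); inputs are
#' arrays with axes (height, width, channel, batch). Kernel entries are
#' Gaussian with standard deviation `1/sqrt(kh*kw*in_channels)`.
#'
#' Grouped convolution is not supported (`groups` must be 1); stride, padding
#' and dilation are.
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel Kernel size, length-2 integer (height, width) or a scalar.
#' @param stride,padding,dilation Spatial hyperparameters (scalars).
#' @param groups Must be 1.
#' @param activation One of `"relu"`, `"identity"`, `"tanh"`.
#' @return An object of class `conv_layer`.
#' @export
conv_layer <- function(in_channels, out_channels, kernel = 3,
                       stride = 1, padding = 0, dilation = 1, groups = 1,
                       activation = "relu") {
  check_activation(activation)
  if (groups != 1) stop("grouped convolution is not supported (groups must be 1)",
                        call. = FALSE)
  kernel <- rep(as.integer(kernel), length.out = 2)
  stopifnot(kernel >= 1, stride >= 1, padding >= 0, dilation >= 1)
  fan_in <- prod(kernel) * in_channels
  W <- array(stats::rnorm(prod(kernel) * in_channels * out_channels,
                          sd = 1 / sqrt(fan_in)),
             dim = c(kernel[1], kernel[2], in_channels, out_channels))
  structure(
    list(
      type = "conv", W = W, b = numeric(out_channels),
      in_channels = in_channels, out_channels = out_channels,
      kernel = kernel, stride = stride, padding = padding,
      dilation = dilation, activation = activation,
      cache = NULL
    ),
    class = c("conv_layer", "pfa_layer")
  )
}

#' Flatten layer
#'
#' Reshapes (height, width, channel, batch) feature maps into a
#' (features x batch) matrix so a dense head can follow convolutional layers.
#' It has no parameters; the backward pass inverts the reshape.
#'
#' @return An object of class `flatten_layer`.
#' @export
flatten_layer <- function() {
  structure(list(type = "flatten", cache = NULL),
            class = c("flatten_layer", "pfa_layer"))
}

#' @export
print.pfa_layer <- function(x, ...) {
  desc <- switch(x$type,
    dense   = sprintf("dense %d -> %d (%s)", x$n_in, x$n_out, x$activation),
    conv    = sprintf("conv %dx%d, %d -> %d ch, stride %d, pad %d (%s)",
                      x$kernel[1], x$kernel[2], x$in_channels, x$out_channels,
                      x$stride, x$padding, x$activation),
    flatten = "flatten"
  )
  cat("<", desc, ">\n", sep = "")
  invisible(x)
}

layer_has_params <- function(layer) layer$type %in% c("dense", "conv")
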