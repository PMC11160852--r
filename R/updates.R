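# Plain-SGD parameter updates with multiplicative weight decay, averaged
# over the minibatch. All updates are additive in the error because the
# error stack carries e = -dLoss/dx.

#' Forward weight update (dense)
#'
#' `W <- (1 - gamma) W + eta * mean_batch(e_{l+1} x_l')`;
#' `b <- b + eta * mean_batch(e_{l+1})`. The bias receives no decay.
#'
#' @param layer A `dense_layer` (its cache is not consulted; pass the inputs
#'   explicitly so the pairing of error and input is visible at the call
#'   site).
#' @param e_next Error at the layer output (`N_{l+1} x batch`).
#' @param x_in Layer input from the same pass (`N_l x batch`).
#' @param eta Learning rate (> 0).
#' @param gamma Weight-decay coefficient in `[0, 1)`.
#' @return The updated layer.
#' @export
update_W <- function(layer, e_next, x_in, eta, gamma = 0) {
  n <- ncol(e_next)
  dW <- tcrossprod(e_next, x_in) / n
  W <- (1 - gamma) * layer$W + eta * dW
  if (any(!is.finite(W))) {
    stop("non-finite forward weight update (dense layer ",
         layer$n_in, " -> ", layer$n_out, ")", call. = FALSE)
  }
  layer$W <- W
  layer$b <- layer$b + eta * rowMeans(e_next)
  layer
}

#' Plastic feedback update (PFA)
#'
#' `R <- (1 - gamma) R + eta * mean_batch(x_l ebar_l')`, followed by
#' re-application of the fixed sparsity mask. `ebar` must be the cached
#' intermediate error of the same minibatch that produced the `W` update.
#'
#' @param fe A feedback entry holding `R` (and optionally `mask_R`).
#' @param x_in Layer-l activations (`N_l x batch`).
#' @param ebar Intermediate error (`Nbar_l x batch`).
#' @inheritParams update_W
#' @return The updated feedback entry.
#' @export
update_R <- function(fe, x_in, ebar, eta, gamma = 0) {
  if (is.null(fe[["R"]])) stop("update_R called for a mode without a plastic R",
                          call. = FALSE)
  n <- ncol(ebar)
  R <- (1 - gamma) * fe[["R"]] + eta * tcrossprod(x_in, ebar) / n
  if (!is.null(fe$mask_R)) R <- apply_mask(R, fe$mask_R)
  if (any(!is.finite(R))) stop("non-finite feedback update", call. = FALSE)
  fe[["R"]] <- R
  fe
}

#' Kolen-Pollack feedback update
#'
#' The feedback matrix receives the transpose of the forward update plus the
#' same weight decay: `R <- (1 - gamma) R + eta * mean_batch(x_l e_{l+1}')`.
#' With shared `eta` and `gamma` the difference `R - W'` decays geometrically
#' at rate `(1 - gamma)`, driving the pathways to symmetry. Implemented via
#' the PFA kernel with `B = I` (so `ebar = e_{l+1}`).
#'
#' @param fe A KP feedback entry holding `R`.
#' @inheritParams update_W
#' @inheritParams update_R
#' @export
update_kp_feedback <- function(fe, e_next, x_in, eta, gamma = 0) {
  update_R(fe, x_in, e_next, eta, gamma)
}

# Conv forward-kernel update: standard kernel-gradient correlation of the
# cached input patches with the output error, plus decay.
update_conv_W <- function(layer, e_next, eta, gamma = 0) {
  ic <- layer$cache$im2col
  n <- dim(e_next)[4]
  dW <- conv_kernel_grad(ic, e_next, layer$kernel[1], layer$kernel[2],
                         layer$in_channels, n)
  W <- (1 - gamma) * layer$W + eta * dW
  if (any(!is.finite(W))) stop("non-finite conv weight update", call. = FALSE)
  layer$W <- W
  layer$b <- layer$b + eta * apply(e_next, 3, sum) / n
  layer
}

update_conv_R <- function(fe, cache_ic, ebar_maps, eta, gamma = 0) {
  n <- dim(ebar_maps)[4]
  dR <- conv_kernel_grad(cache_ic, ebar_maps, dim(fe[["R_kernel"]])[1],
                         dim(fe[["R_kernel"]])[2], dim(fe[["R_kernel"]])[3], n)
  R <- (1 - gamma) * fe[["R_kernel"]] + eta * dR
  if (!is.null(fe$mask_R)) R <- R * fe$mask_R
  if (any(!is.finite(R))) stop("non-finite conv feedback update", call. = FALSE)
  fe[["R_kernel"]] <- R
  fe
}

#' One SGD step over the whole network
#'
#' Applies the forward-weight updates for every parameterized layer and, for
#' PFA/KP modes, the plastic feedback updates, using the error stack from
#' [backward()] and the caches of the preceding [forward()].
#'
#' @param net A `pfa_network` with populated caches.
#' @param feedback A `pfa_feedback` (with `ebar` caches for PFA modes).
#' @param errors Error stack from [backward()].
#' @param eta_w,eta_r Learning rates for `W`/`b` and for `R`.
#' @param gamma_w,gamma_r Weight-decay coefficients, applied multiplicatively
#'   per step.
#' @return A list with the updated `net` and `feedback`.
#' @export
sgd_step <- function(net, feedback, errors, eta_w, eta_r = eta_w,
                     gamma_w = 0, gamma_r = gamma_w) {
  L <- length(net$layers)
  mode <- feedback$mode
  for (i in seq_len(L)) {
    layer <- net$layers[[i]]
    if (layer$type == "dense") {
      net$layers[[i]] <- update_W(layer, errors[[i]], layer$cache$input,
                                  eta_w, gamma_w)
    } else if (layer$type == "conv") {
      net$layers[[i]] <- update_conv_W(layer, errors[[i]], eta_w, gamma_w)
    }
    # plastic feedback serving layer i-1 <- i runs on the same minibatch
    if (i >= 2 && mode %in% c("kp", "pfa", "pfa_o")) {
      fe <- feedback$entries[[i - 1]]
      if (!is.null(fe[["R"]])) {
        x_in <- net$layers[[i]]$cache$input
        feedback$entries[[i - 1]] <- update_R(fe, x_in, fe$ebar, eta_r, gamma_r)
      } else if (!is.null(fe[["R_kernel"]])) {
        feedback$entries[[i - 1]] <- update_conv_R(fe, layer$cache$im2col,
                                                   fe$ebar, eta_r, gamma_r)
      }
    }
  }
  list(net = net, feedback = feedback)
}
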