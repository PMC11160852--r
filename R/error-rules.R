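# Layer-level backward kernels. Each takes the raw error at the layer above
# (per-sample columns), the relevant backward matrix, and the activation
# derivative evaluated at the receiving layer's cached preactivation, and
# returns the error e_l = sigma'(x_l) .* (M e_{l+1}) for the rule's M.
# Sign convention throughout: e = -dLoss/dx, so weight updates are additive.

#' Backpropagation error rule (dense)
#'
#' `e_l = sigma'(x_l) * (W' e_{l+1})`: the exact gradient signal, using the
#' transpose of the forward weights.
#'
#' @param W Forward weight matrix of the layer above (`N_{l+1} x N_l`).
#' @param e_next Error at the layer above (`N_{l+1} x batch`).
#' @param deriv Activation derivative `sigma'` at layer `l`'s cached
#'   preactivation (`N_l x batch`), or `NULL` for a linear layer.
#' @return Error at layer `l` (`N_l x batch`).
#' @export
error_bp <- function(W, e_next, deriv = NULL) {
  g <- crossprod(W, e_next)
  if (!is.null(deriv)) g <- g * deriv
  g
}

#' Feedback alignment error rule (dense)
#'
#' `e_l = sigma'(x_l) * (B e_{l+1})` with a fixed random feedback matrix `B`
#' (`N_l x N_{l+1}`) in place of `W'`.
#'
#' @param B Fixed feedback matrix (`N_l x N_{l+1}`).
#' @inheritParams error_bp
#' @export
error_fa <- function(B, e_next, deriv = NULL) {
  g <- B %*% e_next
  if (!is.null(deriv)) g <- g * deriv
  g
}

#' Direct feedback alignment error rule (dense)
#'
#' `e_l = sigma'(x_l) * (B e_L)`: the output-layer error is projected
#' directly to layer `l` through a fixed random `B` (`N_l x N_L`), skipping
#' the intermediate layers.
#'
#' @param B Fixed feedback matrix (`N_l x N_L`).
#' @param e_out Output-layer error (`N_L x batch`).
#' @inheritParams error_bp
#' @export
error_dfa <- function(B, e_out, deriv = NULL) {
  g <- B %*% e_out
  if (!is.null(deriv)) g <- g * deriv
  g
}

#' Sign-concordant feedback matrix
#'
#' Transports the sign of the current forward weights into the backward
#' path: `B_sf = sign(W') * c`, with one magnitude scalar per layer,
#' `c = mean(|W|)`, recomputed from the current `W` at every backward pass.
#' An optional fixed sparsity mask is applied after the transport.
#'
#' @param W Current forward weight matrix.
#' @param mask Optional binary mask (`N_l x N_{l+1}`).
#' @return The feedback matrix (`N_l x N_{l+1}`).
#' @export
sf_feedback <- function(W, mask = NULL) {
  B <- sign(t(W)) * mean(abs(W))
  if (!is.null(mask)) B <- apply_mask(B, mask)
  B
}

#' Sign-concordant feedback error rule (dense)
#'
#' `e_l = sigma'(x_l) * (B_sf e_{l+1})` with [sf_feedback()] recomputed from
#' the current forward weights.
#'
#' @param W Current forward weight matrix of the layer above.
#' @param mask Optional binary sparsity mask.
#' @inheritParams error_bp
#' @export
error_sf <- function(W, e_next, deriv = NULL, mask = NULL) {
  error_fa(sf_feedback(W, mask), e_next, deriv)
}

#' Product feedback alignment error rule (dense)
#'
#' The backward pathway is factored through an expanded intermediate
#' population: `ebar_l = B e_{l+1}` (fixed random `B`, `Nbar_l x N_{l+1}`),
#' then `e_l = sigma'(x_l) * (R ebar_l)` (plastic `R`, `N_l x Nbar_l`). The
#' intermediate error `ebar` must be kept for the `R` update of the same
#' minibatch. The Kolen-Pollack rule is this kernel with `B = I`.
#'
#' @param B Fixed feedback matrix (`Nbar_l x N_{l+1}`).
#' @param R Plastic feedback matrix (`N_l x Nbar_l`).
#' @inheritParams error_bp
#' @return A list with `ebar` (`Nbar_l x batch`) and `e` (`N_l x batch`).
#' @export
error_pfa <- function(B, R, e_next, deriv = NULL) {
  ebar <- B %*% e_next
  g <- R %*% ebar
  if (!is.null(deriv)) g <- g * deriv
  list(ebar = ebar, e = g)
}

# ---- full-network backward pass ---------------------------------------------

layer_deriv <- function(layer) {
  if (layer$type == "flatten") return(NULL)
  if (is.null(layer$cache)) {
    stop("backward called before forward: layer cache is empty", call. = FALSE)
  }
  act_deriv(layer$activation)(layer$cache$pre)
}

#' Backward pass: full error stack
#'
#' Computes the per-layer errors `e_1 .. e_L` from the output error under the
#' feedback state's algorithm. Requires a preceding [forward()] on the same
#' batch (caches are consumed). For PFA modes the intermediate errors `ebar`
#' are cached in the returned feedback state for the subsequent `R` update.
#'
#' @param net A `pfa_network` with populated forward caches.
#' @param feedback A `pfa_feedback` built for `net`.
#' @param e_out Output error from [output_error()] (`N_L x batch`).
#' @return A list with `errors` (list of per-layer error arrays, index L =
#'   output layer) and `feedback` (with `ebar` caches populated).
#' @export
backward <- function(net, feedback, e_out) {
  stopifnot(inherits(net, "pfa_network"), inherits(feedback, "pfa_feedback"))
  L <- length(net$layers)
  errors <- vector("list", L)
  errors[[L]] <- e_out
  mode <- feedback$mode
  for (i in rev(seq_len(L - 1))) {
    nxt <- net$layers[[i + 1]]
    fe <- if (L >= 2) feedback$entries[[i]] else NULL
    e_next <- errors[[i + 1]]
    deriv <- layer_deriv(net$layers[[i]])

    if (nxt$type == "flatten") {
      g <- array(e_next, dim = nxt$cache$in_dim)
      errors[[i]] <- if (is.null(deriv)) g else g * deriv
      next
    }

    if (nxt$type == "dense") {
      if (mode == "bp") {
        errors[[i]] <- error_bp(nxt$W, e_next, deriv)
      } else if (mode == "fa") {
        errors[[i]] <- error_fa(fe$B, e_next, deriv)
      } else if (mode == "dfa") {
        errors[[i]] <- error_dfa(fe$B, errors[[L]], deriv)
      } else if (mode == "sf") {
        errors[[i]] <- error_sf(nxt$W, e_next, deriv, mask = fe$mask_B)
      } else { # kp, pfa, pfa_o share the product kernel
        res <- error_pfa(fe$B, fe$R, e_next, deriv)
        feedback$entries[[i]]$ebar <- res$ebar
        errors[[i]] <- res$e
      }
    } else { # conv
      dim_x <- dim(nxt$cache$input)
      ic <- nxt$cache$im2col
      if (mode == "bp") {
        g <- conv_input_grad(nxt$W, e_next, ic, dim_x, nxt$padding)
      } else if (mode == "fa") {
        g <- conv_input_grad(fe$B_kernel, e_next, ic, dim_x, nxt$padding)
      } else if (mode %in% c("pfa", "pfa_o")) {
        E <- maps_to_cols(e_next)                       # cout x (oh*ow*N)
        ebar_maps <- cols_to_maps(fe$B %*% E, dim(e_next)[1], dim(e_next)[2],
                                  dim(e_next)[4])
        feedback$entries[[i]]$ebar <- ebar_maps
        g <- conv_input_grad(fe$R_kernel, ebar_maps, ic, dim_x, nxt$padding)
      } else {
        stop("mode '", mode, "' is not implemented for conv layers", call. = FALSE)
      }
      errors[[i]] <- if (is.null(deriv)) g else g * deriv
    }
  }
  list(errors = errors, feedback = feedback)
}
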