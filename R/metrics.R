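#' Alignment angle between two weight configurations
#'
#' The angle, in degrees, between the vectorized matrices (or kernels):
#' `acos(<a, b> / (||a|| ||b||))`. Used as the backward-forward *weight
#' alignment* `angle(vec W', vec B)` for FA/SF and the *path alignment*
#' `angle(vec W', vec RB)` for PFA; 0 degrees means a BP-equivalent backward
#' pathway.
#'
#' @param a,b Numeric matrices, arrays or vectors of equal length; both must
#'   have nonzero norm (a zero-norm input is an error, never silently 0).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
alignment_angle <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have the same length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("alignment angle undefined for zero-norm input", call. = FALSE)
  }
  cosv <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

#' Composed backward pathway
#'
#' Dense case: the product `RB` (`N_l x N_{l+1}`), the effective feedback
#' matrix of the factored pathway. Conv case ([compose_path_conv()]): the
#' contraction of the plastic kernel `R` (`kh, kw, N_l, Nbar`) with the 1x1
#' channel-mixing `B` (`Nbar x N_{l+1}`) over the intermediate axis, giving
#' an effective backward kernel with the forward kernel's layout, directly
#' comparable to `W`.
#'
#' @param R Plastic feedback matrix (`N_l x Nbar`).
#' @param B Fixed feedback matrix (`Nbar x N_{l+1}`).
#' @return The product matrix (dense) or effective kernel (conv).
#' @export
path_matrix <- function(R, B) {
  stopifnot(ncol(R) == nrow(B))
  R %*% B
}

#' @rdname path_matrix
#' @export
compose_path_conv <- function(R, B) {
  d <- dim(R)
  stopifnot(length(d) == 4, d[4] == nrow(B))
  array(matrix(R, prod(d[1:3]), d[4]) %*% B, dim = c(d[1:3], ncol(B)))
}

#' Backward-forward norm ratio
#'
#' `||backward||_F / ||W'||_F` on the vectorized weights: values near 1
#' indicate stable error magnitudes across the backward pathway (neither
#' exploding nor vanishing), the ideal being BP's exact ratio of 1.
#'
#' @param backward Backward matrix (`B`, `B_sf`, or the composed `RB`).
#' @param forward_t The transposed forward weights (or, conv, the forward
#'   kernel) to compare against; must have nonzero norm.
#' @return Nonnegative scalar.
#' @export
norm_ratio <- function(backward, forward_t) {
  nf <- sqrt(sum(as.numeric(forward_t)^2))
  if (nf == 0) stop("norm ratio undefined: forward weights have zero norm",
                    call. = FALSE)
  sqrt(sum(as.numeric(backward)^2)) / nf
}

# Backward matrix/kernel for one feedback entry, in a layout directly
# comparable to the transposed forward weights (dense) or the forward
# kernel (conv). NULL where the mode defines no comparable pathway (BP is
# exactly W'; DFA skips layers).
backward_object <- function(layer_next, fe, mode) {
  if (layer_next$type == "dense") {
    switch(mode,
      bp  = t(layer_next$W),
      fa  = fe$B,
      sf  = sf_feedback(layer_next$W, fe$mask_B),
      kp  = ,
      pfa = ,
      pfa_o = path_matrix(fe$R, fe$B),
      NULL)
  } else if (layer_next$type == "conv") {
    switch(mode,
      bp  = layer_next$W,
      fa  = fe$B_kernel,
      pfa = ,
      pfa_o = compose_path_conv(fe$R_kernel, fe$B),
      NULL)
  } else NULL
}

forward_object <- function(layer_next) {
  if (layer_next$type == "dense") t(layer_next$W) else layer_next$W
}

#' Per-layer alignment diagnostics for a network
#'
#' Computes, for every hidden layer with a defined backward pathway, the
#' weight/path alignment angle and the weight/path norm ratio against the
#' current forward weights.
#'
#' @param net A `pfa_network`.
#' @param feedback The matching `pfa_feedback`.
#' @return A tibble with columns `layer`, `algorithm`, `angle_deg`,
#'   `norm_ratio`.
#' @export
network_alignment <- function(net, feedback) {
  mode <- feedback$mode
  rows <- list()
  for (i in seq_along(feedback$entries)) {
    nxt <- net$layers[[i + 1]]
    if (nxt$type == "flatten") next
    fe <- feedback$entries[[i]]
    bw <- backward_object(nxt, fe, mode)
    if (is.null(bw)) next
    fw <- forward_object(nxt)
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = i, algorithm = mode,
      angle_deg = alignment_angle(fw, bw),
      norm_ratio = norm_ratio(bw, fw)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(layer = integer(), algorithm = character(),
                          angle_deg = numeric(), norm_ratio = numeric()))
  }
  dplyr::bind_rows(rows)
}
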