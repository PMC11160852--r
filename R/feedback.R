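.algorithms <- c("bp", "fa", "dfa", "sf", "kp", "pfa", "pfa_o")

#' Feedback pathway state for a network
#'
#' Builds the per-layer backward-pathway structures required by each
#' credit-assignment rule. Feedback entry `i` serves the computation of the
#' error at layer `i` from the error at layer `i+1` (through layer `i+1`'s
#' forward weights in BP/SF, or through this entry's feedback matrices
#' otherwise).
#'
#' Per mode:
#' \describe{
#'   \item{bp}{no feedback structures (the transpose of `W` is used).}
#'   \item{fa}{one fixed random matrix `B` of shape `(N_l, N_{l+1})` per
#'     hidden layer (for conv layers, a fixed random backward kernel of the
#'     forward kernel's spatial shape).}
#'   \item{dfa}{one fixed random matrix `B` of shape `(N_l, N_L)` per hidden
#'     layer, projecting the output error directly; dense networks only.}
#'   \item{sf}{no stored matrix; the sign of the current forward weights is
#'     transported each backward pass (see [backward()]). A sparsity mask is
#'     stored if requested.}
#'   \item{kp}{a plastic matrix `R` of shape `(N_l, N_{l+1})`, updated
#'     symmetrically to `W` with weight decay; implemented as PFA with
#'     `B = I`.}
#'   \item{pfa, pfa_o}{a fixed random `B` of shape `(Nbar_l, N_{l+1})` into an
#'     expanded intermediate population of `Nbar_l = ceiling(expansion_ratio
#'     * N_{l+1})` neurons, and a plastic `R` of shape `(N_l, Nbar_l)`. For
#'     `pfa` the entries of `B` are i.i.d. Gaussian with variance `1/Nbar_l`;
#'     for `pfa_o` `B` is semi-orthogonal (`B'B = I`). For conv layers `B` is
#'     a 1x1 channel-mixing matrix and `R` a kernel of the forward spatial
#'     shape.}
#' }
#'
#' @param net A `pfa_network` (used for shapes and, for `r_init = "matched"`,
#'   initial weights).
#' @param mode Algorithm tag, one of `"bp"`, `"fa"`, `"dfa"`, `"sf"`, `"kp"`,
#'   `"pfa"`, `"pfa_o"`.
#' @param expansion_ratio Intermediate-population expansion ratio
#'   `1/lambda = Nbar_l / N_{l+1}` for PFA modes (>= 1; default 10).
#' @param sparsity Fraction `p` of feedback entries fixed to zero for the
#'   whole of training, via a mask sampled once here.
#' @param seed Optional integer seed.
#' @param r_init `"random"` (Gaussian, variance `1/Nbar`) or `"matched"`
#'   (`R0 = W0' B'`, which with semi-orthogonal `B` makes the PFA pathway
#'   reproduce BP exactly under shared learning rate and decay).
#' @return An object of class `pfa_feedback`.
#' @export
init_feedback <- function(net, mode, expansion_ratio = 10, sparsity = 0,
                          seed = NULL, r_init = c("random", "matched")) {
  stopifnot(inherits(net, "pfa_network"))
  mode <- match.arg(mode, .algorithms)
  r_init <- match.arg(r_init)
  stopifnot(expansion_ratio >= 1, sparsity >= 0, sparsity < 1)
  if (!is.null(seed)) set.seed(seed)
  L <- length(net$layers)
  types <- vapply(net$layers, `[[`, "", "type")
  if (mode %in% c("dfa", "sf", "kp") && any(types == "conv")) {
    stop("mode '", mode, "' is only implemented for dense networks", call. = FALSE)
  }
  out_dim <- if (types[L] == "dense") net$layers[[L]]$n_out else
    stop("the output layer must be dense", call. = FALSE)

  entries <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    nxt <- net$layers[[i + 1]]
    entries[[i]] <- make_feedback_entry(nxt, mode, expansion_ratio, sparsity,
                                        out_dim, r_init)
  }
  structure(list(mode = mode, entries = entries,
                 expansion_ratio = expansion_ratio, sparsity = sparsity),
            class = "pfa_feedback")
}

make_feedback_entry <- function(nxt, mode, ratio, sparsity, out_dim, r_init) {
  if (nxt$type == "flatten") return(list(kind = "flatten"))
  fe <- list(kind = nxt$type, ebar = NULL)
  rmask <- function(d) (matrix(stats::runif(prod(d)), d[1], d[2]) >= sparsity) * 1

  if (nxt$type == "dense") {
    n_out <- nxt$n_out; n_in <- nxt$n_in
    if (mode == "fa") {
      fe$B <- matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_out)), n_in, n_out)
      fe$mask_B <- rmask(dim(fe$B)); fe$B <- fe$B * fe$mask_B
    } else if (mode == "dfa") {
      fe$B <- matrix(stats::rnorm(n_in * out_dim, sd = 1 / sqrt(out_dim)),
                     n_in, out_dim)
      fe$mask_B <- rmask(dim(fe$B)); fe$B <- fe$B * fe$mask_B
    } else if (mode == "sf") {
      fe$mask_B <- rmask(c(n_in, n_out))
    } else if (mode == "kp") {
      fe$B <- diag(n_out)
      fe$nbar <- n_out
      fe$R <- matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_out)), n_in, n_out)
      fe$mask_R <- rmask(dim(fe$R)); fe$R <- fe$R * fe$mask_R
    } else if (mode %in% c("pfa", "pfa_o")) {
      nbar <- as.integer(ceiling(ratio * n_out))
      fe$nbar <- nbar
      fe$B <- if (mode == "pfa_o") init_semi_orthogonal(nbar, n_out) else
        init_iid_feedback(nbar, n_out)
      fe$mask_B <- rmask(dim(fe$B)); fe$B <- fe$B * fe$mask_B
      fe$R <- if (r_init == "matched") t(nxt$W) %*% t(fe$B) else
        matrix(stats::rnorm(n_in * nbar, sd = 1 / sqrt(nbar)), n_in, nbar)
      fe$mask_R <- rmask(dim(fe$R)); fe$R <- fe$R * fe$mask_R
    }
  } else { # conv
    kh <- nxt$kernel[1]; kw <- nxt$kernel[2]
    cin <- nxt$in_channels; cout <- nxt$out_channels
    if (mode == "fa") {
      fe$B_kernel <- array(stats::rnorm(kh * kw * cin * cout,
                                        sd = 1 / sqrt(kh * kw * cout)),
                           dim = c(kh, kw, cin, cout))
      fe$mask_B <- (array(stats::runif(length(fe$B_kernel)),
                          dim = dim(fe$B_kernel)) >= sparsity) * 1
      fe$B_kernel <- fe$B_kernel * fe$mask_B
    } else if (mode %in% c("pfa", "pfa_o")) {
      nbar <- as.integer(ceiling(ratio * cout))
      fe$nbar <- nbar
      fe$B <- if (mode == "pfa_o") init_semi_orthogonal(nbar, cout) else
        init_iid_feedback(nbar, cout)
      fe$mask_B <- rmask(dim(fe$B)); fe$B <- fe$B * fe$mask_B
      if (r_init == "matched") {
        Wmat <- matrix(nxt$W, kh * kw * cin, cout)
        fe$R_kernel <- array(Wmat %*% t(fe$B), dim = c(kh, kw, cin, nbar))
      } else {
        fe$R_kernel <- array(stats::rnorm(kh * kw * cin * nbar,
                                          sd = 1 / sqrt(kh * kw * nbar)),
                             dim = c(kh, kw, cin, nbar))
      }
      fe$mask_R <- (array(stats::runif(length(fe$R_kernel)),
                          dim = dim(fe$R_kernel)) >= sparsity) * 1
      fe$R_kernel <- fe$R_kernel * fe$mask_R
    }
  }
  fe
}

#' @export
print.pfa_feedback <- function(x, ...) {
  cat("<pfa_feedback mode=", x$mode,
      " expansion_ratio=", x$expansion_ratio,
      " sparsity=", x$sparsity, ">\n", sep = "")
  invisible(x)
}

#' Apply a fixed sparsity mask
#'
#' Entrywise product of a weight matrix (or kernel array) with a binary
#' mask; idempotent. Used to keep masked feedback entries exactly zero after
#' every update.
#'
#' @param matrix Numeric matrix or array.
#' @param mask Binary mask of the same shape.
#' @return The masked matrix.
#' @export
apply_mask <- function(matrix, mask) {
  stopifnot(all(dim(matrix) == dim(mask)))
  matrix * mask
}
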