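# Direct 2-d convolution via patch extraction (im2col) and its adjoint
# (col2im). All backward operators (input gradients, transposed convolution
# for the FA/PFA kernels, kernel gradients) are expressed through the same
# two primitives, so the implicit 180-degree kernel flip of the gradient
# operator comes from the adjacency structure, not from an explicit flip.
#
# Layouts: feature maps (h, w, channel, batch); kernels (kh, kw, in, out).

conv_out_size <- function(n, k, stride, padding, dilation) {
  eff <- (k - 1) * dilation + 1
  out <- (n + 2 * padding - eff) %/% stride + 1
  if (out < 1) stop("kernel does not fit input (output size < 1)", call. = FALSE)
  out
}

pad_maps <- function(x, padding) {
  if (padding == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * padding, d[2] + 2 * padding, d[3], d[4]))
  xp[padding + seq_len(d[1]), padding + seq_len(d[2]), , ] <- x
  xp
}

# Linear indices into the padded array for every (kernel offset, channel) x
# (output position, sample) pair. Returned as a matrix with
# kh*kw*C rows and oh*ow*N columns, shared by im2col and col2im.
patch_indices <- function(dim_p, kh, kw, stride, dilation, oh, ow) {
  Hp <- dim_p[1]; Wp <- dim_p[2]; C <- dim_p[3]; N <- dim_p[4]
  hh <- outer((seq_len(kh) - 1) * dilation + 1, (seq_len(oh) - 1) * stride, "+") # kh x oh
  ww <- outer((seq_len(kw) - 1) * dilation + 1, (seq_len(ow) - 1) * stride, "+") # kw x ow
  # row block structure: (ki, kj, c); column block structure: (i, j, n)
  rows <- kh * kw * C; cols <- oh * ow * N
  idx <- matrix(0L, rows, cols)
  HpWp <- Hp * Wp
  for (c in seq_len(C)) {
    coff <- (c - 1L) * HpWp
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        r <- ki + (kj - 1L) * kh + (c - 1L) * kh * kw
        # position (i,j) -> linear h + (w-1)*Hp within one sample
        lin <- outer(hh[ki, ], (ww[kj, ] - 1L) * Hp, "+") + coff   # oh x ow
        idx[r, ] <- rep(as.integer(lin), times = N) +
          rep((seq_len(N) - 1L) * (HpWp * C), each = oh * ow)
      }
    }
  }
  idx
}

im2col <- function(x, kh, kw, stride, padding, dilation) {
  d <- dim(x)
  oh <- conv_out_size(d[1], kh, stride, padding, dilation)
  ow <- conv_out_size(d[2], kw, stride, padding, dilation)
  xp <- pad_maps(x, padding)
  idx <- patch_indices(dim(xp), kh, kw, stride, dilation, oh, ow)
  Xcol <- matrix(xp[as.vector(idx)], nrow = nrow(idx))
  list(Xcol = Xcol, oh = oh, ow = ow, idx = idx, dim_p = dim(xp))
}

# Adjoint of im2col: scatter-add columns back into the (padded) input shape,
# then crop the padding. For a fixed patch row the target indices are
# distinct, so a vectorized add per row is collision-free.
col2im <- function(Gcol, idx, dim_p, padding, dim_x) {
  acc <- numeric(prod(dim_p))
  for (r in seq_len(nrow(idx))) {
    ii <- idx[r, ]
    acc[ii] <- acc[ii] + Gcol[r, ]
  }
  gp <- array(acc, dim = dim_p)
  if (padding > 0) {
    gp <- gp[padding + seq_len(dim_x[1]), padding + seq_len(dim_x[2]), , ,
             drop = FALSE]
  }
  gp
}

# z[(cout), (i,j,n)] -> array (oh, ow, cout, N)
cols_to_maps <- function(Z, oh, ow, N) {
  cout <- nrow(Z)
  aperm(array(Z, dim = c(cout, oh, ow, N)), c(2, 3, 1, 4))
}

# array (oh, ow, cout, N) -> matrix (cout) x (oh*ow*N)
maps_to_cols <- function(e) {
  d <- dim(e)
  matrix(aperm(e, c(3, 1, 2, 4)), nrow = d[3])
}

#' @export
forward_layer.conv_layer <- function(layer, x) {
  d <- dim(x)
  if (length(d) != 4) stop("conv layer expects (h, w, c, batch) input", call. = FALSE)
  if (d[3] != layer$in_channels) {
    stop(sprintf("conv layer expects %d channels, got %d",
                 layer$in_channels, d[3]), call. = FALSE)
  }
  ic <- im2col(x, layer$kernel[1], layer$kernel[2], layer$stride,
               layer$padding, layer$dilation)
  Wmat <- matrix(layer$W, nrow = prod(layer$kernel) * layer$in_channels)
  Z <- crossprod(Wmat, ic$Xcol) + layer$b            # cout x (oh*ow*N)
  z <- cols_to_maps(Z, ic$oh, ic$ow, d[4])
  a <- act_fun(layer$activation)(z)
  layer$cache <- list(input = x, pre = z, im2col = ic)
  list(layer = layer, out = a)
}

# Input gradient of a convolution whose forward kernel (in W layout
# (kh,kw,cin,cq)) maps cin -> cq channels: given error maps at the output
# resolution (oh, ow, cq, N), return maps at the input resolution. This is
# the transposed-convolution operator carrying the layer's stride, padding
# and dilation; used for BP (kernel = W), FA (kernel = B_fa) and PFA
# (kernel = R, with cq = Nbar).
conv_input_grad <- function(kernel, e_out, cache_ic, dim_x, padding) {
  Kmat <- matrix(kernel, nrow = dim(kernel)[1] * dim(kernel)[2] * dim(kernel)[3])
  E <- maps_to_cols(e_out)                            # cq x (oh*ow*N)
  Gcol <- Kmat %*% E                                  # (kh*kw*cin) x (oh*ow*N)
  col2im(Gcol, cache_ic$idx, cache_ic$dim_p, padding, dim_x)
}

# Kernel gradient, averaged over the batch: correlation of the cached input
# patches with the output-resolution error maps.
conv_kernel_grad <- function(cache_ic, e_out, kh, kw, cin, n_batch) {
  E <- maps_to_cols(e_out)
  G <- tcrossprod(cache_ic$Xcol, E) / n_batch         # (kh*kw*cin) x cq
  array(G, dim = c(kh, kw, cin, ncol(G)))
}
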