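# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: explicit loops for the forward passes and
# central finite differences for gradients.

# A small random MLP with Gaussian weights and biases.
rand_mlp <- function(sizes, activation = "tanh", out_activation = "identity") {
  L <- length(sizes) - 1
  layers <- lapply(seq_len(L), function(l) {
    ly <- dense_layer(sizes[l], sizes[l + 1],
                      activation = if (l == L) out_activation else activation)
    ly$b <- stats::rnorm(sizes[l + 1], sd = 0.2)
    ly
  })
  network(layers)
}

# Loop-based dense forward pass (explicit sums, one sample at a time).
loop_forward_dense <- function(net, x) {
  out <- matrix(NA_real_, 0, 0)
  cols <- if (is.null(dim(x))) 1 else ncol(x)
  x <- matrix(x, ncol = cols)
  res <- NULL
  for (k in seq_len(cols)) {
    v <- x[, k]
    for (layer in net$layers) {
      z <- numeric(layer$n_out)
      for (i in seq_len(layer$n_out)) {
        s <- layer$b[i]
        for (j in seq_len(layer$n_in)) s <- s + layer$W[i, j] * v[j]
        z[i] <- s
      }
      v <- switch(layer$activation,
                  relu = pmax(z, 0), identity = z, tanh = tanh(z))
    }
    res <- cbind(res, v)
  }
  res
}

# Mean softmax cross-entropy of a network on a batch, as a plain function of
# the flattened parameters of one layer (for finite-difference gradients).
net_loss <- function(net, x, y) {
  out <- forward(net, x)$output
  output_error(out, y)$loss
}

fd_weight_grad <- function(net, x, y, layer_idx, h = 1e-6) {
  W <- net$layers[[layer_idx]]$W
  G <- array(0, dim = dim(W))
  for (i in seq_along(W)) {
    np <- net; np$layers[[layer_idx]]$W[i] <- W[i] + h
    nm <- net; nm$layers[[layer_idx]]$W[i] <- W[i] - h
    G[i] <- (net_loss(np, x, y) - net_loss(nm, x, y)) / (2 * h)
  }
  G
}

# Finite-difference error at layer l. The error stack follows the
# preactivation convention (the recursion applies sigma' of the receiving
# layer), so the oracle perturbs layer l's preactivation z_l and maps it
# through sigma_l and the truncated network layers l+1..L.
fd_layer_error <- function(net, x, y, l, h = 1e-6) {
  L <- length(net$layers)
  fwd <- forward(net, x)
  zl <- fwd$net$layers[[l]]$cache$pre
  act <- switch(net$layers[[l]]$activation,
                relu = function(z) pmax(z, 0), identity = function(z) z,
                tanh = tanh)
  tail_net <- network(net$layers[(l + 1):L])
  e <- array(0, dim = dim(zl))
  for (i in seq_along(zl)) {
    vp <- zl; vp[i] <- vp[i] + h
    vm <- zl; vm[i] <- vm[i] - h
    e[i] <- -(net_loss(tail_net, act(vp), y) -
                net_loss(tail_net, act(vm), y)) / (2 * h)
  }
  e
}

forward_layer_oracle <- function(layer, v) {
  z <- layer$W %*% v + layer$b
  switch(layer$activation, relu = pmax(z, 0), identity = z, tanh = tanh(z))
}

# Direct nested-loop 2-d convolution, channel-summed, for one sample.
loop_conv_forward <- function(x, W, b, stride = 1, padding = 0, dilation = 1) {
  d <- dim(x)                      # (h, w, cin, n)
  kd <- dim(W)                     # (kh, kw, cin, cout)
  hp <- d[1] + 2 * padding; wp <- d[2] + 2 * padding
  oh <- (hp - ((kd[1] - 1) * dilation + 1)) %/% stride + 1
  ow <- (wp - ((kd[2] - 1) * dilation + 1)) %/% stride + 1
  out <- array(0, dim = c(oh, ow, kd[4], d[4]))
  for (n in seq_len(d[4])) {
    xp <- matrix(0, hp, wp)
    for (co in seq_len(kd[4])) {
      acc <- array(0, dim = c(oh, ow))
      for (ci in seq_len(d[3])) {
        xp[] <- 0
        xp[padding + seq_len(d[1]), padding + seq_len(d[2])] <- x[, , ci, n]
        for (i in seq_len(oh)) for (j in seq_len(ow)) {
          s <- 0
          for (ki in seq_len(kd[1])) for (kj in seq_len(kd[2])) {
            s <- s + W[ki, kj, ci, co] *
              xp[(i - 1) * stride + (ki - 1) * dilation + 1,
                 (j - 1) * stride + (kj - 1) * dilation + 1]
          }
          acc[i, j] <- acc[i, j] + s
        }
      }
      out[, , co, n] <- acc + b[co]
    }
  }
  out
}

# A tiny conv+dense network for gradient checks.
rand_conv_net <- function(img = 5, cin = 2, cmid = 3, n_classes = 3,
                          kernel = 3, stride = 1, padding = 0, dilation = 1,
                          activation = "tanh") {
  cl <- conv_layer(cin, cmid, kernel = kernel, stride = stride,
                   padding = padding, dilation = dilation,
                   activation = activation)
  oh <- conv_out_size_oracle(img, kernel, stride, padding, dilation)
  dl <- dense_layer(oh * oh * cmid, n_classes, activation = "identity")
  network(list(cl, flatten_layer(), dl))
}

conv_out_size_oracle <- function(n, k, stride, padding, dilation) {
  (n + 2 * padding - ((k - 1) * dilation + 1)) %/% stride + 1
}

fd_conv_kernel_grad <- function(net, x, y, layer_idx = 1, h = 1e-6) {
  W <- net$layers[[layer_idx]]$W
  G <- array(0, dim = dim(W))
  for (i in seq_along(W)) {
    np <- net; np$layers[[layer_idx]]$W[i] <- W[i] + h
    nm <- net; nm$layers[[layer_idx]]$W[i] <- W[i] - h
    G[i] <- (net_loss(np, x, y) - net_loss(nm, x, y)) / (2 * h)
  }
  G
}

# Crafted IDX fixture files (n tiny images + labels), written byte by byte.
write_idx_fixture <- function(dir, images, labels, gzip = FALSE) {
  # images: list of integer matrices (rows x cols, values 0..255)
  n <- length(images)
  r <- nrow(images[[1]]); c <- ncol(images[[1]])
  img_path <- file.path(dir, if (gzip) "imgs-idx3-ubyte.gz" else "imgs-idx3-ubyte")
  lab_path <- file.path(dir, if (gzip) "labs-idx1-ubyte.gz" else "labs-idx1-ubyte")
  con <- if (gzip) gzfile(img_path, "wb") else file(img_path, "wb")
  writeBin(c(2051L, n, r, c), con, size = 4, endian = "big")
  for (m in images) writeBin(as.raw(as.integer(t(m))), con)  # row-major
  close(con)
  con <- if (gzip) gzfile(lab_path, "wb") else file(lab_path, "wb")
  writeBin(c(2049L, n), con, size = 4, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  close(con)
  list(images = img_path, labels = lab_path)
}

# Internal seed-substream derivation, via the package namespace, so tests can
# rebuild the exact network a harness run starts from.
substream_seed_copy <- function(seed, stream) {
  getFromNamespace("substream_seed", "pfanet")(seed, stream)
}

# Two stacked conv layers + dense head: errors must propagate *through* a
# conv layer, exercising the conv feedback pathway (entry 1 is conv).
rand_conv_net2 <- function(img = 6, cin = 1, c1 = 2, c2 = 3, n_classes = 2,
                           s1 = 1, p1 = 1, s2 = 1, p2 = 0,
                           activation = "tanh") {
  l1 <- conv_layer(cin, c1, 3, stride = s1, padding = p1,
                   activation = activation)
  o1 <- conv_out_size_oracle(img, 3, s1, p1, 1)
  l2 <- conv_layer(c1, c2, 3, stride = s2, padding = p2,
                   activation = activation)
  o2 <- conv_out_size_oracle(o1, 3, s2, p2, 1)
  network(list(l1, l2, flatten_layer(),
               dense_layer(o2 * o2 * c2, n_classes, activation = "identity")))
}
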