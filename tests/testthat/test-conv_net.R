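conv_forward_pkg <- function(layer, x) forward(network(list(layer)), x)$output

# Overwrite the dense feedback entry so the error arriving at the conv stack
# is exactly the BP error; the conv entry under test is then the only
# difference between pathways.
match_dense_entry <- function(fb, net) {
  L <- length(net$layers)
  Wd <- net$layers[[L]]$W
  if (fb$mode == "fa") {
    fb$entries[[L - 1]]$B <- t(Wd)
  } else {
    fb$entries[[L - 1]]$B <- diag(nrow(Wd))
    fb$entries[[L - 1]]$R <- t(Wd)
  }
  fb
}

test_that("conv forward matches a nested-loop convolution oracle", {
  set.seed(1)
  cases <- list(
    list(img = 5, cin = 2, cout = 3, k = 3, s = 1, p = 0, d = 1),
    list(img = 6, cin = 1, cout = 2, k = 3, s = 2, p = 1, d = 1),
    list(img = 7, cin = 2, cout = 2, k = 2, s = 1, p = 1, d = 2),
    list(img = 8, cin = 3, cout = 4, k = 3, s = 2, p = 0, d = 1)
  )
  for (cs in cases) {
    ly <- conv_layer(cs$cin, cs$cout, kernel = cs$k, stride = cs$s,
                     padding = cs$p, dilation = cs$d, activation = "identity")
    ly$b <- rnorm(cs$cout)
    x <- array(rnorm(cs$img^2 * cs$cin * 2), dim = c(cs$img, cs$img, cs$cin, 2))
    got <- conv_forward_pkg(ly, x)
    want <- loop_conv_forward(x, ly$W, ly$b, cs$s, cs$p, cs$d)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("1x1 stride-1 conv is a pixelwise dense layer; delta kernel is a channel mix", {
  set.seed(2)
  ly <- conv_layer(3, 2, kernel = 1, activation = "identity")
  x <- array(rnorm(4 * 4 * 3 * 2), dim = c(4, 4, 3, 2))
  got <- conv_forward_pkg(ly, x)
  M <- t(matrix(ly$W, 3, 2))             # 2 x 3 channel map
  for (i in 1:4) for (j in 1:4) for (n in 1:2) {
    expect_equal(got[i, j, , n], as.numeric(M %*% x[i, j, , n] + ly$b),
                 tolerance = 1e-12)
  }

  ly2 <- conv_layer(2, 2, kernel = 3, padding = 1, activation = "identity")
  ly2$W[] <- 0
  ly2$W[2, 2, 1, 1] <- 1; ly2$W[2, 2, 2, 2] <- 2   # center-only kernel
  x2 <- array(rnorm(5 * 5 * 2), dim = c(5, 5, 2, 1))
  got2 <- conv_forward_pkg(ly2, x2)
  expect_equal(got2[, , 1, 1], x2[, , 1, 1], tolerance = 1e-12)
  expect_equal(got2[, , 2, 1], 2 * x2[, , 2, 1], tolerance = 1e-12)
})

test_that("conv layer validates channel mismatch and rejects groups != 1", {
  ly <- conv_layer(2, 3)
  x <- array(0, dim = c(5, 5, 4, 1))
  expect_error(forward(network(list(ly)), x), "channels")
  expect_error(conv_layer(4, 4, groups = 2), "groups")
})

test_that("conv BP errors (through a conv layer) and kernel gradients match finite differences", {
  set.seed(3)
  for (cs in list(list(s2 = 1, p2 = 0), list(s2 = 2, p2 = 1))) {
    net <- rand_conv_net2(img = 5, cin = 1, c1 = 2, c2 = 2, n_classes = 2,
                          s2 = cs$s2, p2 = cs$p2)
    x <- array(rnorm(5 * 5 * 1 * 2), dim = c(5, 5, 1, 2))
    y <- c(1, 2)
    fwd <- forward(net, x)
    oe <- output_error(fwd$output, y)
    bwd <- backward(fwd$net, init_feedback(net, "bp"), oe$e)
    for (l in 1:2) {
      fd <- fd_layer_error(fwd$net, x, y, l)
      expect_equal(bwd$errors[[l]], fd * 2, tolerance = 1e-5)
    }
    up <- sgd_step(fwd$net, init_feedback(net, "bp"), bwd$errors, eta_w = 1)
    for (l in 1:2) {
      dW <- up$net$layers[[l]]$W - net$layers[[l]]$W
      expect_equal(dW, -fd_conv_kernel_grad(net, x, y, layer_idx = l),
                   tolerance = 1e-5)
    }
  }
})

test_that("conv FA with the forward kernel as feedback reduces to conv BP", {
  set.seed(4)
  net <- rand_conv_net2(img = 6, cin = 1, c1 = 2, c2 = 3, s2 = 2, p2 = 1)
  x <- array(rnorm(6 * 6 * 1 * 3), dim = c(6, 6, 1, 3))
  y <- c(1, 2, 1)
  fwd <- forward(net, x)
  oe <- output_error(fwd$output, y)
  fb_fa <- match_dense_entry(init_feedback(net, "fa", seed = 5), net)
  fb_fa$entries[[1]]$B_kernel <- net$layers[[2]]$W
  got <- backward(fwd$net, fb_fa, oe$e)$errors
  want <- backward(fwd$net, init_feedback(net, "bp"), oe$e)$errors
  expect_equal(got[[2]], want[[2]], tolerance = 1e-12)
  expect_equal(got[[1]], want[[1]], tolerance = 1e-12)
})

test_that("conv PFA equals conv FA run with the composed effective kernel", {
  set.seed(6)
  net <- rand_conv_net2(img = 6, cin = 2, c1 = 2, c2 = 3, p2 = 1)
  fb <- match_dense_entry(init_feedback(net, "pfa", expansion_ratio = 3,
                                        seed = 7), net)
  x <- array(rnorm(6 * 6 * 2 * 2), dim = c(6, 6, 2, 2))
  y <- c(2, 1)
  fwd <- forward(net, x)
  oe <- output_error(fwd$output, y)
  got <- backward(fwd$net, fb, oe$e)$errors[[1]]

  fb_fa <- match_dense_entry(init_feedback(net, "fa", seed = 8), net)
  fb_fa$entries[[1]]$B_kernel <- compose_path_conv(fb$entries[[1]]$R_kernel,
                                                   fb$entries[[1]]$B)
  want <- backward(fwd$net, fb_fa, oe$e)$errors[[1]]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("conv PFA with identity 1x1 B and matched R reduces to conv BP", {
  set.seed(9)
  net <- rand_conv_net2(img = 5, cin = 2, c1 = 2, c2 = 3)
  fb <- match_dense_entry(init_feedback(net, "pfa", expansion_ratio = 1,
                                        seed = 10), net)
  fb$entries[[1]]$B <- diag(3)                     # Nbar = cout
  fb$entries[[1]]$R_kernel <- net$layers[[2]]$W
  x <- array(rnorm(5 * 5 * 2 * 2), dim = c(5, 5, 2, 2))
  y <- c(1, 2)
  fwd <- forward(net, x)
  oe <- output_error(fwd$output, y)
  got <- backward(fwd$net, fb, oe$e)$errors[[1]]
  want <- backward(fwd$net, init_feedback(net, "bp"), oe$e)$errors[[1]]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("conv PFA-o with matched init reproduces conv BP for a training run", {
  set.seed(11)
  net <- rand_conv_net2(img = 6, cin = 1, c1 = 2, c2 = 2, activation = "relu")
  fb <- init_feedback(net, "pfa_o", expansion_ratio = 4, seed = 12,
                      r_init = "matched")
  net_bp <- net
  fb_bp <- init_feedback(net_bp, "bp")
  x_all <- array(rnorm(6 * 6 * 1 * 40), dim = c(6, 6, 1, 40))
  y_all <- sample(2, 40, replace = TRUE)
  for (step in 1:12) {
    idx <- ((step - 1) %% 4) * 10 + 1:10
    x <- x_all[, , , idx, drop = FALSE]; y <- y_all[idx]
    f1 <- forward(net, x); f2 <- forward(net_bp, x)
    expect_equal(f1$output, f2$output, tolerance = 1e-8)
    oe <- output_error(f1$output, y)
    b1 <- backward(f1$net, fb, oe$e)
    b2 <- backward(f2$net, fb_bp, output_error(f2$output, y)$e)
    expect_equal(b1$errors[[1]], b2$errors[[1]], tolerance = 1e-8)
    expect_equal(b1$errors[[2]], b2$errors[[2]], tolerance = 1e-8)
    u1 <- sgd_step(f1$net, b1$feedback, b1$errors, eta_w = 0.05, gamma_w = 1e-3)
    net <- u1$net; fb <- u1$feedback
    u2 <- sgd_step(f2$net, b2$feedback, b2$errors, eta_w = 0.05, gamma_w = 1e-3)
    net_bp <- u2$net
    # the conv pathway identity: composed kernel equals the forward kernel
    expect_equal(compose_path_conv(fb$entries[[1]]$R_kernel, fb$entries[[1]]$B),
                 net$layers[[2]]$W, tolerance = 1e-8)
  }
})

test_that("conv PFA trains a synthetic conv task to within 10% of BP's final loss", {
  d <- gen_conv_task(image_size = 6, n_channels = 1, n_classes = 2,
                     n_samples = 240, seed = 13, n_test = 0)
  run <- function(alg) {
    set.seed(14)
    net <- network(list(
      conv_layer(1, 4, kernel = 3, padding = 1, activation = "relu"),
      conv_layer(4, 4, kernel = 3, activation = "relu"),
      flatten_layer(),
      dense_layer(4 * 4 * 4, 2, activation = "identity")
    ))
    cfg <- train_config(algorithm = alg, epochs = 12, batch_size = 24,
                        lr = 0.05, wd_initial = 1e-3, wd_main = 1e-4,
                        expansion_ratio = 10, seed = 15)
    fit <- train_network(d, cfg, net = net)
    fit$history$train_loss[nrow(fit$history)]
  }
  loss_bp <- run("bp")
  loss_pfa <- run("pfa")
  expect_lt(loss_pfa, loss_bp * 1.10 + 1e-12)
})
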