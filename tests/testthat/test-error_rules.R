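make_stack <- function(net, feedback, x, y) {
  fwd <- forward(net, x)
  oe <- output_error(fwd$output, y)
  list(net = fwd$net, bwd = backward(fwd$net, feedback, oe$e), oe = oe)
}

test_that("layer kernels: zero upstream error gives zero error everywhere", {
  set.seed(1)
  W <- matrix(rnorm(12), 4, 3)
  z <- matrix(0, 3, 2)
  expect_true(all(error_bp(W, matrix(0, 4, 2)) == 0))
  expect_true(all(error_fa(t(W), matrix(0, 4, 2)) == 0))
  expect_true(all(error_dfa(matrix(rnorm(6), 3, 2), matrix(0, 2, 2)) == 0))
  pf <- error_pfa(B = matrix(rnorm(8), 2, 4), R = matrix(rnorm(6), 3, 2),
                  e_next = matrix(0, 4, 2))
  expect_true(all(pf$ebar == 0) && all(pf$e == 0))
})

test_that("FA with B = W' and PFA with B = I, R = W' reduce to BP", {
  set.seed(2)
  W <- matrix(rnorm(20), 5, 4)
  e_next <- matrix(rnorm(10), 5, 2)
  deriv <- matrix(runif(8), 4, 2)
  bp <- error_bp(W, e_next, deriv)
  expect_equal(error_fa(t(W), e_next, deriv), bp)
  pf <- error_pfa(B = diag(5), R = t(W), e_next = e_next, deriv = deriv)
  expect_equal(pf$e, bp)
  expect_equal(pf$ebar, e_next)
})

test_that("PFA error equals the pre-multiplied product-matrix pathway", {
  set.seed(3)
  for (rep in 1:10) {
    nl <- sample(2:6, 1); nn <- sample(2:6, 1); nbar <- sample(4:12, 1)
    B <- matrix(rnorm(nbar * nn), nbar, nn)
    R <- matrix(rnorm(nl * nbar), nl, nbar)
    e_next <- matrix(rnorm(nn * 3), nn, 3)
    deriv <- matrix(runif(nl * 3), nl, 3)
    pf <- error_pfa(B, R, e_next, deriv)
    expect_equal(pf$e, error_fa(path_matrix(R, B), e_next, deriv),
                 tolerance = 1e-12)
  }
})

test_that("SF feedback transports the sign of the forward weights", {
  set.seed(4)
  W <- matrix(rnorm(30), 5, 6)
  B <- sf_feedback(W)
  expect_equal(sign(B), sign(t(W)))
  expect_equal(unique(abs(as.numeric(B))), mean(abs(W)))

  Wpos <- abs(W)
  expect_true(all(sf_feedback(Wpos) == mean(Wpos)))
  Wd <- diag(c(2, -3, 4))
  expect_equal(sf_feedback(Wd), diag(sign(c(2, -3, 4)) * mean(abs(Wd))))
})

test_that("DFA projects the output error through a loop-checked matrix product", {
  set.seed(5)
  B <- matrix(rnorm(4 * 3), 4, 3)
  eL <- matrix(rnorm(3 * 2), 3, 2)
  deriv <- matrix(runif(8), 4, 2)
  want <- matrix(0, 4, 2)
  for (k in 1:2) for (i in 1:4) {
    s <- 0
    for (j in 1:3) s <- s + B[i, j] * eL[j, k]
    want[i, k] <- s * deriv[i, k]
  }
  expect_equal(error_dfa(B, eL, deriv), want, tolerance = 1e-12)
})

test_that("full BP error stack matches finite-difference gradients -dL/dx_l", {
  set.seed(6)
  for (rep in 1:5) {
    sizes <- c(4, sample(3:5, 2, replace = TRUE), 3)
    net <- rand_mlp(sizes, activation = "tanh")
    x <- matrix(rnorm(4 * 2), 4, 2)
    y <- sample(3, 2, replace = TRUE)
    fb <- init_feedback(net, "bp")
    st <- make_stack(net, fb, x, y)
    for (l in 1:(length(net$layers) - 1)) {
      fd <- fd_layer_error(st$net, x, y, l)
      # fd differentiates the batch-mean loss; the stack is per-sample
      expect_equal(st$bwd$errors[[l]], fd * ncol(x), tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
})

test_that("backward before forward is a state error", {
  net <- rand_mlp(c(3, 3, 2))
  fb <- init_feedback(net, "bp")
  expect_error(backward(net, fb, matrix(0, 2, 1)), "cache")
})

test_that("PFA-o with matched init tracks BP exactly for a whole training run", {
  set.seed(7)
  net <- rand_mlp(c(6, 10, 8, 4), activation = "relu")
  fb <- init_feedback(net, "pfa_o", expansion_ratio = 3, seed = 8,
                      r_init = "matched")
  net_bp <- net
  fb_bp <- init_feedback(net_bp, "bp")
  x_all <- matrix(rnorm(6 * 60), 6, 60)
  y_all <- sample(4, 60, replace = TRUE)
  eta <- 0.05; gamma <- 1e-3
  for (step in 1:30) {
    idx <- ((step - 1) %% 6) * 10 + 1:10
    x <- x_all[, idx]; y <- y_all[idx]
    st <- make_stack(net, fb, x, y)
    st_bp <- make_stack(net_bp, fb_bp, x, y)
    # identical errors (hence identical updates) at every layer
    for (l in seq_along(st$bwd$errors)) {
      expect_equal(st$bwd$errors[[l]], st_bp$bwd$errors[[l]], tolerance = 1e-9)
    }
    up <- sgd_step(st$net, st$bwd$feedback, st$bwd$errors, eta_w = eta,
                   gamma_w = gamma)
    net <- up$net; fb <- up$feedback
    up_bp <- sgd_step(st_bp$net, st_bp$bwd$feedback, st_bp$bwd$errors,
                      eta_w = eta, gamma_w = gamma)
    net_bp <- up_bp$net
    # the pathway identity RB = W' holds after every update
    for (l in 1:(length(net$layers) - 1)) {
      fe <- fb$entries[[l]]
      expect_equal(path_matrix(fe$R, fe$B), t(net$layers[[l + 1]]$W),
                   tolerance = 1e-9)
    }
  }
})

test_that("PFA with frozen R implements FA with fixed feedback R0 B0", {
  set.seed(9)
  net <- rand_mlp(c(5, 7, 3), activation = "tanh")
  fb <- init_feedback(net, "pfa", expansion_ratio = 4, seed = 10)
  R0B0 <- path_matrix(fb$entries[[1]]$R, fb$entries[[1]]$B)
  net_fa <- net
  fb_fa <- init_feedback(net_fa, "fa", seed = 11)
  fb_fa$entries[[1]]$B <- R0B0  # FA with the frozen product as feedback

  x_all <- matrix(rnorm(5 * 40), 5, 40)
  y_all <- sample(3, 40, replace = TRUE)
  for (step in 1:10) {
    idx <- ((step - 1) %% 4) * 10 + 1:10
    st <- make_stack(net, fb, x_all[, idx], y_all[idx])
    st_fa <- make_stack(net_fa, fb_fa, x_all[, idx], y_all[idx])
    expect_equal(st$bwd$errors[[1]], st_fa$bwd$errors[[1]], tolerance = 1e-12)
    up <- sgd_step(st$net, st$bwd$feedback, st$bwd$errors,
                   eta_w = 0.1, eta_r = 0, gamma_w = 1e-3, gamma_r = 0)
    net <- up$net; fb <- up$feedback
    up_fa <- sgd_step(st_fa$net, st_fa$bwd$feedback, st_fa$bwd$errors,
                      eta_w = 0.1, gamma_w = 1e-3)
    net_fa <- up_fa$net
    expect_equal(net$layers[[2]]$W, net_fa$layers[[2]]$W, tolerance = 1e-12)
  }
})

test_that("KP with symmetric init stays exactly symmetric under shared eta and decay", {
  set.seed(12)
  net <- rand_mlp(c(4, 6, 3), activation = "relu")
  fb <- init_feedback(net, "kp", seed = 13)
  fb$entries[[1]]$R <- t(net$layers[[2]]$W)
  x_all <- matrix(rnorm(4 * 30), 4, 30)
  y_all <- sample(3, 30, replace = TRUE)
  for (step in 1:15) {
    idx <- ((step - 1) %% 3) * 10 + 1:10
    st <- make_stack(net, fb, x_all[, idx], y_all[idx])
    up <- sgd_step(st$net, st$bwd$feedback, st$bwd$errors,
                   eta_w = 0.05, gamma_w = 1e-3)
    net <- up$net; fb <- up$feedback
    expect_equal(fb$entries[[1]]$R, t(net$layers[[2]]$W), tolerance = 1e-12)
  }
})
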