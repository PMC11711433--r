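# The reverse-mode engine is the foundation of every model; each primitive's
# analytic gradient is checked against central finite differences.

grad_check <- function(build, x, tol = 1e-6) {
  p <- tokenmixer:::ad_param(x)
  loss <- build(p)
  tokenmixer:::ad_backward(loss)
  num <- numerical_grad(function(v) tokenmixer:::ad_value(build(tokenmixer:::ad_const(v))), x)
  expect_lt(max(abs(p$grad - num)), tol)
}

test_that("linear-algebra primitives backpropagate exact gradients", {
  set.seed(42)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_matmul(p, tokenmixer:::ad_const(B))), A)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_matmul(tokenmixer:::ad_const(A), p)), B)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(p, p)), A)
  bias <- rnorm(4)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_add_rowvec(p, tokenmixer:::ad_const(bias))), A)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_add_rowvec(tokenmixer:::ad_const(A), p)), bias)
})

test_that("activations and softmax backpropagate exact gradients", {
  set.seed(7)
  X <- matrix(rnorm(12), 3, 4)
  w <- rnorm(4)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_gelu(p)), X)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(tokenmixer:::ad_sigmoid(p), p)), X)
  # weighted softmax keeps the row-coupling in play
  grad_check(function(p) {
    s <- tokenmixer:::ad_softmax_rows(p)
    tokenmixer:::ad_sum(tokenmixer:::ad_mul(s, tokenmixer:::ad_const(matrix(w, 3, 4, byrow = TRUE))))
  }, X, tol = 1e-5)
})

test_that("normalization layers backpropagate exact gradients", {
  set.seed(11)
  X <- matrix(rnorm(24), 4, 6)
  gam <- runif(6, 0.5, 1.5); bet <- rnorm(6)
  grad_check(function(p) {
    tokenmixer:::ad_sum(tokenmixer:::ad_mul(
      tokenmixer:::ad_layernorm_rows(p, tokenmixer:::ad_const(gam), tokenmixer:::ad_const(bet)),
      tokenmixer:::ad_const(matrix(seq_len(24) / 24, 4, 6))))
  }, X, tol = 1e-5)
  # batchnorm in training mode, including the batch-statistic coupling
  Xc <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  st <- new.env(); st$running_mean <- numeric(2); st$running_var <- rep(1, 2)
  wgt <- array(runif(36), c(2, 3, 3, 2))
  grad_check(function(p) {
    st2 <- new.env(); st2$running_mean <- numeric(2); st2$running_var <- rep(1, 2)
    tokenmixer:::ad_sum(tokenmixer:::ad_mul(
      tokenmixer:::ad_batchnorm(p, tokenmixer:::ad_const(c(1.2, 0.7)),
                                tokenmixer:::ad_const(c(0.1, -0.2)), st2, training = TRUE),
      tokenmixer:::ad_const(wgt)))
  }, Xc, tol = 1e-4)
})

test_that("convolutions backpropagate exact gradients", {
  set.seed(13)
  X <- array(rnorm(1 * 6 * 6 * 2), c(1, 6, 6, 2))
  W <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)) * 0.3
  b <- rnorm(3)
  wgt_same <- array(runif(6 * 6 * 3), c(1, 6, 6, 3))
  f <- function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_conv2d(p, tokenmixer:::ad_const(W), tokenmixer:::ad_const(b),
                           stride = 1L, padding = "same"),
    tokenmixer:::ad_const(wgt_same)))
  grad_check(f, X, tol = 1e-5)
  fw <- function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_conv2d(tokenmixer:::ad_const(X), p, tokenmixer:::ad_const(b),
                           stride = 1L, padding = "same"),
    tokenmixer:::ad_const(wgt_same)))
  grad_check(fw, W, tol = 1e-5)
  # strided valid convolution (patch-embedding stem shape)
  W2 <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4)) * 0.3
  wgt_val <- array(runif(3 * 3 * 4), c(1, 3, 3, 4))
  g <- function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_conv2d(p, tokenmixer:::ad_const(W2), NULL, stride = 2L, padding = "valid"),
    tokenmixer:::ad_const(wgt_val)))
  grad_check(g, X, tol = 1e-5)
  # depthwise
  Wd <- array(rnorm(3 * 3 * 2), c(3, 3, 2)) * 0.4
  bd <- rnorm(2)
  wgt_dw <- array(runif(6 * 6 * 2), c(1, 6, 6, 2))
  h1 <- function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_depthwise_conv2d(p, tokenmixer:::ad_const(Wd), tokenmixer:::ad_const(bd)),
    tokenmixer:::ad_const(wgt_dw)))
  grad_check(h1, X, tol = 1e-5)
  h2 <- function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_depthwise_conv2d(tokenmixer:::ad_const(X), p, tokenmixer:::ad_const(bd)),
    tokenmixer:::ad_const(wgt_dw)))
  grad_check(h2, Wd, tol = 1e-5)
})

test_that("reductions, reshapes and losses backpropagate exact gradients", {
  set.seed(17)
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  wgt <- matrix(runif(6), 2, 3)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_mean_axis(p, 2L), tokenmixer:::ad_const(wgt))), X, tol = 1e-6)
  L <- matrix(rnorm(10), 5, 2)
  y1 <- diag(2)[sample(1:2, 5, replace = TRUE), ]
  grad_check(function(p) tokenmixer:::ad_softmax_crossentropy(p, y1), L, tol = 1e-5)
  Lb <- matrix(rnorm(5), 5, 1)
  yb <- sample(0:1, 5, replace = TRUE)
  grad_check(function(p) tokenmixer:::ad_sigmoid_bce(p, yb), Lb, tol = 1e-5)
  wr <- matrix(runif(24), 4, 6)
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_reshape(p, c(4, 6)), tokenmixer:::ad_const(wr))),
    array(rnorm(24), c(2, 4, 3)), tol = 1e-6)
})

test_that("channel broadcast multiply matches manual computation and gradients", {
  set.seed(19)
  X <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  M <- array(runif(20), c(4, 5, 1))
  out <- tokenmixer:::ad_mul_bcast_channel(tokenmixer:::ad_const(X), tokenmixer:::ad_const(M))
  manual <- X * as.vector(M)
  expect_equal(tokenmixer:::ad_value(out), manual)
  wgt <- array(runif(60), c(4, 5, 3))
  grad_check(function(p) tokenmixer:::ad_sum(tokenmixer:::ad_mul(
    tokenmixer:::ad_mul_bcast_channel(tokenmixer:::ad_const(X), p), tokenmixer:::ad_const(wgt))),
    M, tol = 1e-5)
})
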