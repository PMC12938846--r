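# Finite-difference checks of every tape operation the network relies on.
# Each builder maps an input node to a scalar-ish root; fd_gradcheck
# compares the analytic input gradient against central differences.

ad <- function(name) get(name, envir = asNamespace("spineloc"))

test_that("elementwise / linear ops backpropagate correctly", {
  set.seed(1)
  x0 <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_matmul")(g, x, ad_const_t(g, W)), x0), 1e-5)
  expect_lt(fd_gradcheck(function(g, x) ad("ad_relu")(g, x), x0 + 0.05), 1e-5)
  expect_lt(fd_gradcheck(function(g, x) ad("ad_sigmoid")(g, x), x0), 1e-5)
  expect_lt(fd_gradcheck(function(g, x) ad("ad_softmax_rows")(g, x), x0), 1e-5)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_add_bias")(g, x, ad_const_t(g, c(0.3, -0.2))), x0 %*% W), 1e-5)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_gather_rows")(g, x, c(2L, 2L, 1L)), x0), 1e-5)
})

test_that("conv2d matches finite differences for inputs, weights and bias", {
  set.seed(2)
  x0 <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  W0 <- matrix(rnorm(18 * 3, sd = 0.5), 18, 3)
  b0 <- rnorm(3)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_conv2d")(g, x, ad_const_t(g, W0), ad_const_t(g, b0)), x0), 1e-5)
  expect_lt(fd_gradcheck(function(g, W)
    ad("ad_conv2d")(g, ad_const_t(g, x0), W, ad_const_t(g, b0)), W0), 1e-5)
  ## 1x1 convolution path
  W1 <- matrix(rnorm(2 * 4), 2, 4)
  b1 <- rnorm(4)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_conv2d")(g, x, ad_const_t(g, W1), ad_const_t(g, b1), k = 1L),
    x0), 1e-5)
})

test_that("conv3d forward matches a brute-force loop and backpropagates", {
  set.seed(3)
  dims <- c(4, 3, 5)
  x0 <- array(rnorm(prod(dims) * 2), c(dims, 2))
  W0 <- matrix(rnorm(2 * 27 * 2, sd = 0.3), 54, 2)
  b0 <- rnorm(2)
  g <- ad_tape_t()
  y <- ad("ad_conv3d")(g, ad_const_t(g, x0), ad_const_t(g, W0), ad_const_t(g, b0))
  ## brute force with zero padding
  ref <- array(0, c(dims, 2))
  for (a in 1:4) for (b in 1:3) for (cc in 1:5) for (co in 1:2) {
    acc <- b0[co]
    for (ch in 1:2) for (dc in -1:1) for (db in -1:1) for (da in -1:1) {
      aa <- a + da; bb <- b + db; ccc <- cc + dc
      if (aa < 1 || aa > 4 || bb < 1 || bb > 3 || ccc < 1 || ccc > 5) next
      row <- (ch - 1) * 27 + (dc + 1) * 9 + (db + 1) * 3 + (da + 1) + 1
      acc <- acc + x0[aa, bb, ccc, ch] * W0[row, co]
    }
    ref[a, b, cc, co] <- acc
  }
  expect_equal(y$value, ref, tolerance = 1e-12)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_conv3d")(g, x, ad_const_t(g, W0), ad_const_t(g, b0)), x0), 1e-5)
  expect_lt(fd_gradcheck(function(g, W)
    ad("ad_conv3d")(g, ad_const_t(g, x0), W, ad_const_t(g, b0)), W0), 1e-5)
})

test_that("pooling and resampling ops backpropagate correctly", {
  set.seed(4)
  x0 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_lt(fd_gradcheck(function(g, x) ad("ad_maxpool2d")(g, x, 2L), x0), 1e-5)
  A <- spineloc:::interp_matrix(12, 8)
  B <- spineloc:::avg_matrix(4, 8)
  expect_lt(fd_gradcheck(function(g, x) ad("ad_resample_sep")(g, x, A, B), x0),
            1e-5)
  uv <- cbind(runif(20, -1, 8), runif(20, -1, 8))
  expect_lt(fd_gradcheck(function(g, x) ad("ad_sample_bilinear")(g, x, uv), x0),
            1e-5)
})

test_that("soft-argmax and voxel softmax backpropagate correctly", {
  set.seed(5)
  grid <- volume_grid_cube(16, 4)
  centers <- voxel_centers(grid)
  x0 <- rnorm(64)
  expect_lt(fd_gradcheck(function(g, x)
    ad("ad_softargmax3d")(g, x, centers, 1.3), x0), 1e-4)
  expect_lt(fd_gradcheck(function(g, x) ad("ad_softmax_vec")(g, x, 0.7), x0),
            1e-5)
  ## value agrees with the numeric soft-argmax
  g <- ad_tape_t()
  n <- ad("ad_softargmax3d")(g, ad_const_t(g, x0), centers, 2)
  expect_equal(n$value, soft_argmax3d(array(x0, c(4, 4, 4)), grid, 2),
               tolerance = 1e-12)
})

test_that("multi-head attention block backpropagates and shares the tape correctly", {
  set.seed(6)
  pars <- list()
  pars <- spineloc:::init_mha_block(pars, "t", d = 4, hidden = 8, heads = 2)
  q0 <- matrix(rnorm(12), 3, 4)
  kv <- matrix(rnorm(20), 5, 4)
  expect_lt(fd_gradcheck(function(g, x)
    spineloc:::mha_block(g, pars, "t", x, ad_const_t(g, kv), 2, 8), q0), 1e-5)
  ## gradient reaches the parameters through ad_grads
  g <- ad_tape_t()
  out <- spineloc:::mha_block(g, pars, "t", ad_const_t(g, q0),
                              ad_const_t(g, kv), 2, 8)
  spineloc:::ad_backward(g, out)
  gr <- spineloc:::ad_grads(g)
  expect_true(all(c("t.q1.W", "t.k2.W", "t.v1.W", "t.o.W", "t.f1.W") %in% names(gr)))
  expect_gt(sum(abs(gr[["t.q1.W"]])), 0)
})

test_that("shared parameters accumulate gradients across uses", {
  pars <- list(w = matrix(1.5, 1, 1))
  g <- ad_tape_t()
  x <- ad_const_t(g, matrix(2, 1, 1))
  w1 <- spineloc:::ad_param(g, pars, "w")
  w2 <- spineloc:::ad_param(g, pars, "w")
  y <- ad("ad_add")(g, ad("ad_matmul")(g, x, w1), ad("ad_matmul")(g, x, w2))
  spineloc:::ad_backward(g, y)
  expect_equal(as.numeric(spineloc:::ad_grads(g)$w), 4)  # 2 + 2
})
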