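# Shared primitives: activations, conv/norm/act unit, SPPF.

test_that("hard sigmoid and hard swish match their piecewise definition", {
  expect_equal(hard_sigmoid(0), 0.5)
  expect_equal(hard_sigmoid(3), 1.0)
  expect_equal(hard_sigmoid(-3), 0.0)
  expect_equal(h_swish(0), 0.0)
  expect_equal(h_swish(5), 5.0)       # identity above saturation
  expect_equal(h_swish(1), 4 / 6, tolerance = 1e-12)
  # monotone non-decreasing gate, continuity/Lipschitz on a grid
  xs <- seq(-6, 6, by = 1e-3)
  expect_true(all(diff(hard_sigmoid(xs)) >= 0))
  hs <- h_swish(xs)
  L <- max(abs(diff(hs)) / 1e-3)
  expect_lt(L, 3.01)                  # |h_swish'| <= (2*6+3)/6 on [-6,6]
  expect_lt(max(abs(diff(hs))), 0.0031)
})

test_that("conv unit respects the shape contract and rejects even kernels", {
  set.seed(1)
  x <- rfm(8, 16, 16)
  m <- conv_bn_act(8, 16, k = 3, s = 2)
  expect_equal(dim(ag_value(forward(m, x))), c(8, 8, 1, 16))
  m1 <- conv_bn_act(3, 2, k = 1, s = 1)
  expect_equal(dim(ag_value(forward(m1, rfm(3, 4, 4)))), c(4, 4, 1, 2))
  expect_error(conv_bn_act(3, 4, k = 2), "odd")
  # closed-form parameter count: bias-free conv + per-channel affine norm
  expect_equal(n_parameters(conv_bn_act(2, 4, k = 3)), 2 * 4 * 9 + 2 * 4)
})

test_that("identity-initialized conv unit reproduces its input", {
  set.seed(2)
  m <- conv_bn_act(3, 3, k = 3, s = 1, act = "identity")
  w <- array(0, dim = c(3, 3, 3, 3))
  for (c in 1:3) w[2, 2, c, c] <- 1
  m$w$value <- w
  x <- rfm(3, 6, 6)
  y <- ag_value(forward(m, x))        # eval mode: running stats are (0, 1)
  expect_equal(y, x, tolerance = 1e-5)
})

test_that("SPPF preserves shape and pools constants and peaks correctly", {
  set.seed(3)
  m <- sppf(64)
  x <- rfm(64, 8, 8)
  y <- ag_value(forward(m, x))
  expect_equal(dim(y), c(8, 8, 1, 64))
  # max pooling of a constant map is the map itself
  const <- array(2.5, c(5, 5, 1, 4))
  expect_equal(ag_value(longandet:::op_maxpool_same(const, 5)), const)
  # a single peak propagates to every cell within the pool radius
  peak <- array(0, c(5, 5, 1, 1)); peak[3, 3, 1, 1] <- 7
  pooled <- ag_value(longandet:::op_maxpool_same(peak, 5))
  expect_true(all(pooled == 7))       # radius 2 covers the whole 5x5 grid
  peak9 <- array(0, c(9, 9, 1, 1)); peak9[5, 5, 1, 1] <- 7
  pooled9 <- ag_value(longandet:::op_maxpool_same(peak9, 5))
  expect_equal(pooled9[5, 1, 1, 1], 0)     # outside radius
  expect_equal(pooled9[5, 3, 1, 1], 7)     # inside radius
})

test_that("array ops backpropagate correctly (spot checks vs central differences)", {
  set.seed(4)
  ag_set_training(TRUE)
  on.exit(ag_set_training(FALSE))
  x <- longandet:::ag_leaf(rfm(3, 6, 6, 2), requires_grad = TRUE)
  m <- conv_bn_act(3, 5, k = 3, s = 2, act = "silu")
  y <- forward(m, x)
  loss <- longandet:::ag_node(sum(ag_value(y)^2), list(y),
                              function(g) list(2 * ag_value(y) * as.numeric(g)))
  longandet:::ag_backward(loss)
  f <- function() longandet:::ag_no_grad(sum(ag_value(forward(m, x$value))^2))
  num <- function(env, idx, h = 1e-5) {
    old <- env$value
    v <- old; v[idx] <- v[idx] + h; env$value <- v; fp <- f()
    v <- old; v[idx] <- v[idx] - h; env$value <- v; fm <- f()
    env$value <- old
    (fp - fm) / (2 * h)
  }
  for (idx in list(matrix(c(2, 3, 1, 2), 1), matrix(c(5, 1, 2, 3), 1)))
    expect_equal(x$grad[idx], num(x, idx), tolerance = 1e-5)
  iw <- matrix(c(1, 2, 2, 3), 1)
  expect_equal(m$w$grad[iw], num(m$w, iw), tolerance = 1e-5)
  expect_equal(m$bn$beta$grad[4], num(m$bn$beta, 4), tolerance = 1e-5)
})
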