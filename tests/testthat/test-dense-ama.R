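# DenseAMA stage: dense connectivity, transition down-sampling, composition.

test_that("dense layer appends growth_rate channels and keeps the skip exact", {
  set.seed(20)
  cfg <- dense_config(growth_rate = 8L)
  x <- rfm(16, 8, 8)
  ly <- dense_layer_ama(16, cfg)
  y <- ag_value(forward(ly, x))
  expect_equal(dim(y), c(8, 8, 1, 24))
  # dense connectivity: first C_in channels bit-identical to the input
  expect_identical(y[, , , 1:16], x[, , , 1:16])
  # stacking three layers: C0 + 3 * growth
  cc <- 16L
  z <- x
  for (i in 1:3) {
    z <- forward(dense_layer_ama(cc, cfg), z)
    cc <- cc + 8L
  }
  expect_equal(dim(ag_value(z))[4], 40)
  # zero input: the skip block stays exactly zero, branch is deterministic
  z0 <- ag_value(forward(ly, array(0, c(8, 8, 1, 16))))
  expect_identical(z0[, , , 1:16, drop = FALSE], array(0, c(8, 8, 1, 16)))
})

test_that("transition halves spatial size and averages 2x2 blocks", {
  set.seed(21)
  cfg <- dense_config(out_channels = 64L)
  tr <- transit_ama(40, cfg)
  y <- ag_value(forward(tr, rfm(40, 16, 16)))
  expect_equal(dim(y), c(8, 8, 1, 64))
  expect_error(forward(tr, rfm(40, 15, 16)), "even")
  # constant input stays constant through average pooling
  const <- array(3, c(4, 4, 1, 2))
  expect_equal(ag_value(longandet:::op_avgpool2(const)), array(3, c(2, 2, 1, 2)))
  # 2x2 checkerboard of {0, 4} averages to 2 everywhere
  cb <- array(rep(c(0, 4), 8), c(4, 4, 1, 1))   # rows alternate 0 / 4
  expect_equal(ag_value(longandet:::op_avgpool2(cb)), array(2, c(2, 2, 1, 1)))
})

test_that("stage composes layers + transition and matches closed-form params", {
  set.seed(22)
  cfg <- dense_config(in_channels = 32L, growth_rate = 8L, num_layers = 2L,
                      bottleneck_factor = 4L, out_channels = 64L)
  st <- dense_ama_stage(cfg)
  y <- ag_value(forward(st, rfm(32, 32, 32)))
  expect_equal(dim(y), c(16, 16, 1, 64))
  # closed-form parameter count
  layer_params <- function(cin) {
    bw <- cfg$bottleneck_factor * cfg$growth_rate
    2 * cin + cin * bw + 2 * bw + 9 * bw * cfg$growth_rate +
      kernel_from_channels(cfg$growth_rate)
  }
  cc <- 32L
  expected <- 0
  for (i in 1:2) { expected <- expected + layer_params(cc); cc <- cc + 8L }
  expected <- expected + 2 * cc + kernel_from_channels(cc) + cc * 64
  expect_equal(n_parameters(st), expected)
  # forcing every attention gate open changes no shapes
  st$layers[[1]]$ama$gate_on <- FALSE
  st$layers[[2]]$ama$gate_on <- FALSE
  st$transit$ama$gate_on <- FALSE
  expect_equal(dim(ag_value(forward(st, rfm(32, 32, 32)))), c(16, 16, 1, 64))
})
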