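# Assembled detector: shapes, accounting identities, determinism, NMS.

test_that("nano model builds, runs, and produces three scale maps", {
  m <- build_model(nano_config(), seed = 1)
  x <- array(0, c(160, 160, 1, 3))
  outs <- longandet:::ag_no_grad(forward(m, x))
  expect_length(outs, 3)
  expect_equal(dim(ag_value(outs[[1]]$reg)), c(20, 20, 1, 64))
  expect_equal(dim(ag_value(outs[[2]]$cls)), c(10, 10, 1, 1))
  expect_equal(dim(ag_value(outs[[3]]$reg)), c(5, 5, 1, 64))
  # evaluation-mode forward is deterministic, bit-exact
  o2 <- longandet:::ag_no_grad(forward(m, x))
  expect_identical(ag_value(outs[[1]]$reg), ag_value(o2[[1]]$reg))
})

test_that("parameter report is additive and exact for a known conv", {
  m <- build_model(nano_config(), seed = 2)
  rep_ <- count_parameters(m)
  expect_equal(rep_$total, sum(rep_$per_module))
  expect_equal(rep_$total, n_parameters(m))
  expect_equal(n_parameters(conv_bn_act(2, 4, 3)), 80)
})

test_that("flop meter matches closed forms and scales with area", {
  # one 1x1 conv, 4 -> 4 channels, on an 8x8 input:
  # 2 * (k^2 * c_in * c_out * H * W) = 2 * (1 * 4 * 4 * 64) = 2048 FLOPs
  x <- array(0, c(8, 8, 1, 4))
  w <- longandet:::ag_leaf(array(0, c(1, 1, 4, 4)))
  longandet:::ag_flops_start()
  longandet:::op_conv2d(x, w, NULL, stride = 1L)
  expect_equal(longandet:::ag_flops_stop(), 2 * 4 * 4 * 64)
  # doubling both input dimensions quadruples the 2-D conv FLOPs; only the
  # spatial-size-free attention 1-D convs break exactness
  m <- build_model(nano_config(), seed = 3)
  f160 <- count_flops(m, c(160, 160))
  f320 <- count_flops(m, c(320, 320))
  expect_equal(f320 / f160, 4, tolerance = 1e-4)
  expect_error(count_flops(m, c(100, 100)), "32")
})

test_that("untrained model with a high threshold returns a valid empty result", {
  m <- build_model(nano_config(), seed = 4)
  imgs <- array(runif(160 * 160 * 2 * 3), c(160, 160, 2, 3))
  dets <- forward_predict(m, imgs, conf_thresh = 0.99)
  expect_true(is.data.frame(dets))
  expect_equal(nrow(dets), 0)
  expect_error(forward_predict(m, array(0, c(100, 100, 1, 3))), "divisible")
})

test_that("NMS collapses duplicates and matches the all-pairs oracle", {
  d <- data.frame(image = 1, class = 0L, score = c(0.9, 0.9, 0.8),
                  cx = c(0.5, 0.5, 0.52), cy = c(0.5, 0.5, 0.5),
                  w = 0.2, h = 0.2)
  kept <- nms_boxes(d, 0.45)
  expect_equal(nrow(kept), 1)
  set.seed(70)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    d <- data.frame(image = 1, class = sample(0:1, n, TRUE),
                    score = runif(n),
                    cx = runif(n, 0.3, 0.7), cy = runif(n, 0.3, 0.7),
                    w = runif(n, 0.1, 0.4), h = runif(n, 0.1, 0.4))
    a <- nms_boxes(d, 0.45)
    b <- brute_nms(d, 0.45)
    expect_equal(a[order(-a$score), c("cx", "score")],
                 b[, c("cx", "score")], ignore_attr = TRUE)
  }
})

test_that("ablation variants order as printed and the baseline is heaviest", {
  pm <- function(cfg) count_parameters(build_model(cfg, seed = 1))$total
  base <- pm(baseline_config())
  fast <- pm(model_config(use_dense = FALSE, use_faster = TRUE, use_vov = FALSE))
  vov <- pm(model_config(use_dense = FALSE, use_faster = FALSE, use_vov = TRUE))
  full <- pm(longan_config())
  expect_true(full < fast && fast < vov && vov < base)
})
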