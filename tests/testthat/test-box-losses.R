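# Inner-SIoU loss components, comparators, and analytic gradients.

test_that("inner box scales symmetrically about the center", {
  ib <- inner_box(box(0.5, 0.5, 0.4, 0.2), ratio = 1)
  expect_equal(unlist(ib), c(l = 0.3, r = 0.7, t = 0.4, b = 0.6))
  ib5 <- inner_box(box(0.5, 0.5, 0.4, 0.2), ratio = 0.5)
  expect_equal(unlist(ib5), c(l = 0.4, r = 0.6, t = 0.45, b = 0.55))
  ib15 <- inner_box(box(0, 0, 2, 2), ratio = 1.5)
  expect_equal(ib15$l, -1.5)
  expect_equal(ib15$r, 1.5)
  expect_error(inner_box(box(0, 0, 1, 1), ratio = 2), "ratio")
})

test_that("inner IoU reproduces the worked pair and clamps disjoint overlap", {
  b <- box(0.30, 0.30, 0.20, 0.20)
  g <- box(0.40, 0.40, 0.20, 0.20)
  expect_equal(inner_iou(b, b, 0.7), 1.0)
  expect_equal(inner_iou(b, g, 1.0), 1 / 7, tolerance = 1e-12)
  expect_equal(inner_iou(b, g, 0.5), 0)          # inner boxes disjoint
  expect_equal(inner_iou(box(0, 0, 0, 0), box(1, 1, 0, 0)), 0)  # zero union
})

test_that("angle cost hits its stated limits", {
  b <- box(0.2, 0.5, 0.1, 0.1)
  expect_equal(angle_cost(b, box(0.8, 0.5, 0.1, 0.1)), 0)            # horizontal
  expect_equal(angle_cost(b, box(0.5, 0.8, 0.1, 0.1)), 1)            # 45 degrees
  expect_equal(angle_cost(b, b), 0)                                  # coincident
  expect_equal(angle_cost(b, box(0.2, 0.9, 0.1, 0.1)), 0, tolerance = 1e-12) # vertical
  xs <- replicate(50, {
    g <- box(runif(1), runif(1), 0.1, 0.1)
    angle_cost(b, g)
  })
  expect_true(all(xs >= 0 & xs <= 1))
})

test_that("distance and shape costs match scalar evaluation", {
  b <- box(0.30, 0.30, 0.20, 0.20)
  g <- box(0.40, 0.40, 0.20, 0.20)
  expect_equal(distance_cost(b, b), 0)
  lam <- angle_cost(b, g)
  expect_equal(lam, 1)
  expect_equal(distance_cost(b, g, lam), 2 * (1 - exp(-(1 / 3)^2)),
               tolerance = 1e-12)                      # ~ 0.2103
  # monotone in center offset along either axis
  ds <- vapply(seq(0, 0.3, by = 0.01), function(off)
    distance_cost(box(0.3 + off, 0.3, 0.2, 0.2), box(0.3, 0.3, 0.2, 0.2)), 0)
  expect_true(all(diff(ds) >= 0))
  # shape cost
  expect_equal(shape_cost(box(0, 0, 0.2, 0.3), box(1, 1, 0.4, 0.3), theta = 4),
               (1 - exp(-0.5))^4, tolerance = 1e-12)   # ~ 0.0240
  expect_equal(shape_cost(b, g), 0)
  expect_lte(shape_cost(box(0, 0, 1e-9, 1e-9), box(0, 0, 5, 5)),
             2 * (1 - exp(-1))^4)
})

test_that("total loss composes the pieces and vanishes iff boxes coincide", {
  b <- box(0.30, 0.30, 0.20, 0.20)
  g <- box(0.40, 0.40, 0.20, 0.20)
  l <- inner_siou_loss(b, g)
  expect_equal(l$total, 1 - 1 / 7 + (2 * (1 - exp(-1 / 9))) / 2, tolerance = 1e-12)
  expect_equal(round(l$total, 4), 0.9623)
  expect_equal(l$total, 1 - l$iou_inner + (l$distance + l$shape) / 2)
  expect_equal(inner_siou_loss(b, b)$total, 0)
  # strictly positive for any distinct pair
  set.seed(50)
  for (i in 1:25) {
    bb <- box(runif(1), runif(1), runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    gg <- box(runif(1), runif(1), runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    expect_gt(inner_siou_loss(bb, gg)$total, 0)
  }
  # non-increasing along the straight path of centers
  path <- seq(0, 1, length.out = 50)
  tot <- vapply(path, function(t)
    inner_siou_loss(box(0.3 + 0.1 * t, 0.3 + 0.1 * t, 0.2, 0.2), g)$total, 0)
  expect_true(all(diff(tot) <= 1e-12))
  # finite for degenerate zero-area boxes
  expect_true(is.finite(inner_siou_loss(box(0.2, 0.2, 0, 0), g)$total))
  expect_true(is.finite(inner_siou_loss(box(0.2, 0.2, 0, 0.3), box(0.2, 0.2, 0.4, 0))$total))
})

test_that("analytic gradient agrees with central differences", {
  set.seed(51)
  params <- siou_params(ratio = 1.0)
  nchecked <- 0
  for (i in 1:60) {
    b <- c(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
           runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    g <- c(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
           runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    pr <- sample(c(0.6, 1.0, 1.3), 1)
    pp <- siou_params(ratio = pr)
    ga <- inner_siou_grad(b, g, pp)
    for (q in 1:4) {
      h <- 1e-6
      bp <- b; bp[q] <- bp[q] + h
      bm <- b; bm[q] <- bm[q] - h
      gn <- (inner_siou_loss(bp, g, pp)$total -
             inner_siou_loss(bm, g, pp)$total) / (2 * h)
      # skip kink neighborhoods where the subgradient is one-sided
      if (abs(gn - inner_siou_grad(bm, g, pp)[q]) > 1e-3 &&
          abs(gn - inner_siou_grad(bp, g, pp)[q]) > 1e-3) next
      nchecked <- nchecked + 1
      expect_equal(ga[q], gn, tolerance = 1e-4)
    }
  }
  expect_gt(nchecked, 150)
})

test_that("comparator losses behave canonically", {
  b <- box(0.3, 0.3, 0.2, 0.2)
  for (k in c("ciou", "diou", "eiou", "giou"))
    expect_equal(iou_family(b, b, k), 0)
  set.seed(52)
  for (i in 1:50) {
    bb <- box(runif(1), runif(1), runif(1, 0.05, 0.4), runif(1, 0.05, 0.4))
    gg <- box(runif(1), runif(1), runif(1, 0.05, 0.4), runif(1, 0.05, 0.4))
    iou_loss <- 1 - inner_iou(bb, gg, 1)
    expect_gte(iou_family(bb, gg, "giou") + 1e-12, iou_loss)  # giou <= iou
    for (k in c("ciou", "diou", "eiou"))
      expect_gte(iou_family(bb, gg, k) + 1e-12, iou_loss)
  }
  # disjoint boxes inside a common enclosure, vs the pixel-counting oracle
  a <- c(10 / 64, 10 / 64, 8 / 64, 8 / 64)
  d <- c(40 / 64, 40 / 64, 16 / 64, 16 / 64)
  expect_equal(inner_iou(a, d, 1), raster_iou(a, d), tolerance = 1e-3)
  expect_equal(iou_family(a, d, "giou"), 1 - raster_giou(a, d), tolerance = 1e-3)
})
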