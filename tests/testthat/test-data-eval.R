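# Label I/O, augmentation protocol, splits, metrics, scene accuracy,
# synthetic data generator.

test_that("label files roundtrip losslessly and reject bad input", {
  tf <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.1", tf)
  b <- read_labels(tf)
  expect_equal(b, data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.1))
  set.seed(60)
  boxes <- data.frame(class = sample(0:3, 100, TRUE),
                      cx = round(runif(100), 6), cy = round(runif(100), 6),
                      w = round(runif(100), 6), h = round(runif(100), 6))
  write_labels(boxes, tf)
  expect_equal(read_labels(tf), boxes)
  writeLines(c("0 0.5 0.5 0.2 0.1", "0 0.5 oops 0.2 0.1"), tf)
  expect_error(read_labels(tf), "line 2")
  writeLines("0 1.2 0.5 0.2 0.1", tf)
  expect_error(read_labels(tf), "out-of-range")
})

test_that("horizontal flip mirrors boxes and is an involution", {
  set.seed(61)
  img <- array(runif(8 * 10 * 3), c(8, 10, 3))
  boxes <- data.frame(class = 0L, cx = c(0.3, 0.5), cy = c(0.2, 0.6),
                      w = c(0.1, 0.2), h = c(0.1, 0.3))
  f <- flip_lr(img, boxes)
  expect_equal(f$boxes$cx, c(0.7, 0.5))          # centered box invariant
  expect_equal(f$boxes[, c("cy", "w", "h")], boxes[, c("cy", "w", "h")])
  ff <- flip_lr(f$image, f$boxes)
  expect_equal(ff$image, img)
  expect_equal(ff$boxes, boxes)
})

test_that("brightness flag acts as a gamma exponent", {
  img <- array(0.5, c(2, 2, 3))
  expect_equal(brightness_adjust(img, 1), img)
  expect_equal(brightness_adjust(img, 0.3)[1], 0.5^0.3, tolerance = 1e-12)
  expect_gt(brightness_adjust(img, 0.3)[1], 0.5)     # highlights brighten
  flags <- c(0.3, 0.5, 1.0, 1.5, 3.0)
  vals <- vapply(flags, function(f) brightness_adjust(img, f)[1], 0)
  expect_true(all(diff(vals) < 0))                   # darker as flag grows
  expect_error(brightness_adjust(img, 0.1), "flag")
})

test_that("augmentation reproduces the expansion arithmetic", {
  recs <- lapply(seq_len(438), function(i)
    list(image = sprintf("im%03d.png", i),
         boxes = data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)))
  m <- manifest(recs)
  aug <- augment_dataset(m, table_augment_spec(), seed = 1)
  expect_equal(n_records(aug), 438 + 438 + 1584)
  prov <- vapply(aug$records, function(r) sub(":.*", "", r$provenance), "")
  expect_equal(sum(prov == "flip"), 438)
  expect_equal(sum(prov == "brightness"), 1584)
  # all emitted boxes stay within [0, 1]
  allb <- do.call(rbind, lapply(aug$records, function(r) r$boxes))
  expect_true(all(allb[, c("cx", "cy", "w", "h")] >= 0 &
                  allb[, c("cx", "cy", "w", "h")] <= 1))
  # zero-count spec leaves the manifest unchanged
  noop <- augment_dataset(m, table_augment_spec(0L, c(0L, 0L, 0L, 0L)), seed = 1)
  expect_equal(n_records(noop), 438)
  expect_error(augment_dataset(manifest(recs[1:10]),
                               table_augment_spec(n_flip = 20L)), "flips")
})

test_that("splits conserve records, are disjoint and seed-deterministic", {
  recs <- lapply(seq_len(2460), function(i) list(image = sprintf("%d.png", i),
                                                 boxes = data.frame()))
  m <- manifest(recs)
  sp <- split_dataset(m, train_fraction = 0.8, seed = 3)
  expect_equal(n_records(sp$train), 1968)
  expect_equal(n_records(sp$test), 492)
  tr_ids <- vapply(sp$train$records, function(r) r$image, "")
  te_ids <- vapply(sp$test$records, function(r) r$image, "")
  expect_length(intersect(tr_ids, te_ids), 0)
  sp2 <- split_dataset(m, train_fraction = 0.8, seed = 3)
  expect_identical(vapply(sp2$train$records, function(r) r$image, ""), tr_ids)
  folds <- split_dataset(m, k_folds = 5, seed = 4)
  expect_equal(vapply(folds, n_records, 0L), rep(492L, 5))
  ids <- lapply(folds, function(f) vapply(f$records, function(r) r$image, ""))
  expect_equal(sort(unlist(ids)), sort(vapply(recs, function(r) r$image, "")))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(ids[[i]], ids[[j]]), 0)
})

test_that("mean average precision handles the canonical cases", {
  gts <- data.frame(image = 1, class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  perfect <- cbind(gts, score = 1.0)[, c("image", "class", "score", "cx", "cy", "w", "h")]
  ev <- compute_map(perfect, gts)
  expect_equal(ev$map50, 1)
  expect_equal(ev$recall, 1)
  none <- perfect[0, ]
  ev0 <- compute_map(none, gts)
  expect_equal(ev0$map50, 0)
  expect_equal(ev0$recall, 0)
  # 1 GT, a false positive scored above the true positive: AP@0.5 = 0.5
  dets <- data.frame(image = 1, class = 0L, score = c(0.9, 0.8),
                     cx = c(0.9, 0.5), cy = c(0.9, 0.5),
                     w = c(0.05, 0.2), h = c(0.05, 0.2))
  expect_equal(compute_map(dets, gts)$map50, 0.5)
  expect_warning(compute_map(perfect, gts[0, ]), "empty")
})

test_that("scene-count accuracy reproduces the field-test arithmetic", {
  counts <- data.frame(
    scene = c("close_sunny", "close_night", "far_sunny", "far_night"),
    true = c(7L, 9L, 15L, 17L),
    correct = c(7L, 8L, 13L, 14L),
    wrong = c(0L, 1L, 2L, 3L))
  sa <- scene_accuracy(counts)
  expect_equal(sa$per_scene$accuracy,
               100 * c(7 / 7, 8 / 9, 13 / 15, 14 / 17))
  # agreement with the printed one-decimal percentages (82.35 prints as 82.3)
  expect_true(all(abs(sa$per_scene$accuracy - c(100, 88.9, 86.7, 82.3)) < 0.06))
  expect_equal(sa$overall, 100 * 42 / 48)
  expect_equal(sa$overall, 87.5)
  expect_error(scene_accuracy(data.frame(scene = "x", true = 0L,
                                         correct = 0L, wrong = 0L)))
})

test_that("synthetic orchard generator is seed-deterministic with valid boxes", {
  d1 <- file.path(tempdir(), "so1"); d2 <- file.path(tempdir(), "so2")
  m1 <- synth_orchard(seed = 9, n_images = 3, size = 96, dir = d1)
  m2 <- synth_orchard(seed = 9, n_images = 3, size = 96, dir = d2)
  expect_equal(n_records(m1), 3)
  for (i in 1:3) {
    expect_identical(readBin(m1$records[[i]]$image, "raw", 1e6),
                     readBin(m2$records[[i]]$image, "raw", 1e6))
    expect_identical(m1$records[[i]]$boxes, m2$records[[i]]$boxes)
    expect_gte(nrow(m1$records[[i]]$boxes), 1)
    b <- m1$records[[i]]$boxes
    expect_true(all(b[, c("cx", "cy", "w", "h")] >= 0 &
                    b[, c("cx", "cy", "w", "h")] <= 1))
  }
  # manifest roundtrip through the directory convention
  mr <- read_manifest(d1)
  expect_equal(n_records(mr), 3)
  # label files carry 6 decimals
  expect_equal(mr$records[[2]]$boxes, m1$records[[2]]$boxes, tolerance = 1e-5)
})

test_that("emitted boxes enclose the rendered cluster pixels", {
  # single cluster, no occluder, neutral lighting: fruit pixels are exactly
  # the warm-colored ones, so their bounding box is recoverable by color
  m <- synth_orchard(seed = 13, n_images = 4, size = 96,
                     clusters_range = c(1, 1), occluder_prob = 0,
                     lighting_flags = 1)
  for (r in m$records) {
    img <- longandet:::load_image(r$image)
    mask <- img[, , 1] > img[, , 2]            # red over green: fruit
    hit <- which(mask, arr.ind = TRUE)
    S <- dim(img)[1]
    pix_box <- c((min(hit[, 2]) + max(hit[, 2])) / 2 / S,
                 (min(hit[, 1]) + max(hit[, 1])) / 2 / S,
                 (max(hit[, 2]) - min(hit[, 2]) + 1) / S,
                 (max(hit[, 1]) - min(hit[, 1]) + 1) / S)
    b <- as.numeric(r$boxes[1, c("cx", "cy", "w", "h")])
    expect_gte(plain_iou(b, pix_box), 0.9)
  }
})

test_that("package AP agrees with the brute-force enumerator", {
  set.seed(62)
  for (rep in 1:40) {
    sc <- rand_scene(rep)
    got <- compute_map(sc$dets, sc$gts, iou_thresholds = 0.5)
    cls <- sort(unique(sc$gts$class))
    want <- mean(vapply(cls, function(cl)
      brute_ap(sc$dets[sc$dets$class == cl, , drop = FALSE],
               sc$gts[sc$gts$class == cl, , drop = FALSE], 0.5), 0))
    expect_equal(got$map50, want, tolerance = 1e-9)
  }
})
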