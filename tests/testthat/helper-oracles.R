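# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: pixel-counting IoU on grid-aligned boxes,
# re-matching average precision from scratch per rank, and all-pairs NMS.

rfm <- function(C, H, W, N = 1L) array(rnorm(H * W * N * C), c(H, W, N, C))

# Exact IoU by pixel counting. Boxes must have all edges on multiples of
# 1 / grid_unit so the rasterization is exact; res must be a multiple of
# grid_unit.
raster_iou <- function(a, b, grid_unit = 64L, res = 256L) {
  ind <- function(lo, hi) {
    cells <- (seq_len(res) - 0.5) / res
    cells > lo & cells < hi
  }
  ax <- ind(a[1] - a[3] / 2, a[1] + a[3] / 2)
  ay <- ind(a[2] - a[4] / 2, a[2] + a[4] / 2)
  bx <- ind(b[1] - b[3] / 2, b[1] + b[3] / 2)
  by <- ind(b[2] - b[4] / 2, b[2] + b[4] / 2)
  inter <- sum(ay & by) * sum(ax & bx)
  areaA <- sum(ay) * sum(ax)
  areaB <- sum(by) * sum(bx)
  uni <- areaA + areaB - inter
  if (uni == 0) return(0)
  inter / uni
}

# generalized IoU by pixel counting (grid-aligned boxes)
raster_giou <- function(a, b, res = 256L) {
  ind <- function(lo, hi) {
    cells <- (seq_len(res) - 0.5) / res
    cells > lo & cells < hi
  }
  ax <- ind(a[1] - a[3] / 2, a[1] + a[3] / 2); ay <- ind(a[2] - a[4] / 2, a[2] + a[4] / 2)
  bx <- ind(b[1] - b[3] / 2, b[1] + b[3] / 2); by <- ind(b[2] - b[4] / 2, b[2] + b[4] / 2)
  inter <- sum(ax & bx) * sum(ay & by)
  uni <- sum(ax) * sum(ay) + sum(bx) * sum(by) - inter
  ex <- ind(min(a[1] - a[3] / 2, b[1] - b[3] / 2), max(a[1] + a[3] / 2, b[1] + b[3] / 2))
  ey <- ind(min(a[2] - a[4] / 2, b[2] - b[4] / 2), max(a[2] + a[4] / 2, b[2] + b[4] / 2))
  carea <- sum(ex) * sum(ey)
  iou <- if (uni > 0) inter / uni else 0
  if (carea > 0) iou - (carea - uni) / carea else iou
}

# random box with all edges on the 1/64 grid, fully inside [0, 1]
rand_grid_box <- function(unit = 64L) {
  w <- sample(2:24, 1) / unit
  h <- sample(2:24, 1) / unit
  x1 <- sample(0:(unit - w * unit), 1) / unit
  y1 <- sample(0:(unit - h * unit), 1) / unit
  c(x1 + w / 2, y1 + h / 2, w, h)
}

plain_iou <- function(a, b) {
  iw <- max(0, min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
               max(a[1] - a[3] / 2, b[1] - b[3] / 2))
  ih <- max(0, min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
               max(a[2] - a[4] / 2, b[2] - b[4] / 2))
  inter <- iw * ih
  uni <- a[3] * a[4] + b[3] * b[4] - inter
  if (uni <= 0) 0 else inter / uni
}

# Brute-force average precision: for every rank k, re-run the greedy
# matching from scratch on the top-k detections, then integrate the
# precision envelope by explicit maximization over later ranks.
brute_ap <- function(dets, gts, thr = 0.5) {
  if (nrow(dets) == 0) return(0)
  o <- order(-dets$score, dets$image)
  dets <- dets[o, , drop = FALSE]
  ngt <- nrow(gts)
  match_topk <- function(k) {
    used <- rep(FALSE, ngt)
    tp <- 0L
    for (i in seq_len(k)) {
      best <- 0; bj <- 0
      for (j in seq_len(ngt)) {
        if (used[j] || gts$image[j] != dets$image[i]) next
        iou <- plain_iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                         as.numeric(gts[j, c("cx", "cy", "w", "h")]))
        if (iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0 && best >= thr) { used[bj] <- TRUE; tp <- tp + 1L }
    }
    tp
  }
  n <- nrow(dets)
  tp <- vapply(seq_len(n), match_topk, 0L)
  prec <- tp / seq_len(n)
  rec <- tp / ngt
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * max(prec[k:n])
      prev_r <- rec[k]
    }
  }
  ap
}

# All-pairs NMS oracle: a detection survives iff no higher-scored surviving
# detection of the same class overlaps it above the threshold.
brute_nms <- function(dets, thr = 0.45) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  n <- nrow(dets)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !alive[j] || dets$class[j] != dets$class[i]) next
      iou <- plain_iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                       as.numeric(dets[j, c("cx", "cy", "w", "h")]))
      if (iou > thr) alive[j] <- FALSE
    }
  }
  dets[alive, , drop = FALSE]
}

# random tiny detection scene for the metric oracle
rand_scene <- function(img_id, max_boxes = 5L) {
  ng <- sample(1:max_boxes, 1)
  gts <- data.frame(image = img_id, class = sample(0:1, ng, replace = TRUE),
                    cx = runif(ng, 0.2, 0.8), cy = runif(ng, 0.2, 0.8),
                    w = runif(ng, 0.05, 0.3), h = runif(ng, 0.05, 0.3))
  nd <- sample(0:max_boxes, 1)
  dets <- if (nd == 0) {
    data.frame(image = integer(0), class = integer(0), score = numeric(0),
               cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  } else {
    base <- gts[sample(ng, nd, replace = TRUE), , drop = FALSE]
    data.frame(image = img_id, class = sample(0:1, nd, replace = TRUE),
               score = runif(nd),
               cx = base$cx + rnorm(nd, 0, 0.05),
               cy = base$cy + rnorm(nd, 0, 0.05),
               w = pmax(0.02, base$w + rnorm(nd, 0, 0.04)),
               h = pmax(0.02, base$h + rnorm(nd, 0, 0.04)))
  }
  list(dets = dets, gts = gts)
}
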