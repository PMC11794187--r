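# Synthetic orchard-image generator: textured green canopy backgrounds with
# clumps of shaded circles standing in for fruit clusters, optional
# elongated occluder strokes, and gamma lighting variants. Exact ground
# truth boxes are derived from the rendered cluster pixel masks, so the
# labels are correct by construction. Everything is reproducible from one
# integer seed.

smooth_noise <- function(h, w, passes = 3L) {
  m <- matrix(stats::rnorm(h * w), h, w)
  for (i in seq_len(passes)) {
    m <- (m +
      m[c(1, seq_len(h - 1)), ] + m[c(seq_len(h - 1) + 1, h), ] +
      m[, c(1, seq_len(w - 1))] + m[, c(seq_len(w - 1) + 1, w)]) / 5
  }
  (m - min(m)) / (max(m) - min(m) + 1e-12)
}

draw_disc <- function(img, cx, cy, rad, col, shade = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(1L, floor(cx - rad)); x1 <- min(w, ceiling(cx + rad))
  y0 <- max(1L, floor(cy - rad)); y1 <- min(h, ceiling(cy + rad))
  if (x0 > x1 || y0 > y1) return(list(img = img, mask = NULL))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  rr <- sqrt(dx^2 + dy^2)
  inside <- rr <= rad
  # simple spherical shading: brighter toward the upper-left rim
  lum <- shade * (0.55 + 0.45 * pmax(0, 1 - rr / rad) *
                    (1 - 0.4 * (dx + dy) / (rad + 1e-9)))
  for (c in 1:3) {
    plane <- img[ys, xs, c]
    plane[inside] <- pmin(1, col[c] * lum[inside])
    img[ys, xs, c] <- plane
  }
  list(img = img, mask = list(ys = ys, xs = xs, inside = inside))
}

#' Generate a synthetic orchard detection dataset
#'
#' Each image is a textured green background with `clusters_range[1]` to
#' `clusters_range[2]` fruit clusters, every cluster a clump of 5-20 shaded
#' circles in fruit-like colors. With probability `occluder_prob` an
#' elongated branch-colored stroke crosses a cluster. A per-image gamma
#' lighting flag is sampled from `lighting_flags`. Ground-truth boxes are
#' the bounding boxes of each cluster's rendered pixels; images are written
#' as PNG with side-car label files plus an index file.
#'
#' @param seed integer seed; the dataset is byte-identical given the seed.
#' @param n_images number of images.
#' @param size square image side in pixels, divisible by 32.
#' @param clusters_range integer range of clusters per image.
#' @param occluder_prob probability that a cluster is crossed by an
#'   occluder stroke.
#' @param lighting_flags vector of gamma flags to sample from (1 = neutral).
#' @param dir output directory (created); defaults to a session temp dir.
#' @return a [manifest()] whose records carry image paths and boxes.
#' @export
synth_orchard <- function(seed = 0L, n_images = 8L, size = 320L,
                          clusters_range = c(1L, 6L), occluder_prob = 0.3,
                          lighting_flags = c(0.35, 0.65, 1.0, 1.35, 2.75),
                          dir = NULL) {
  if (size %% 32 != 0) stop("size must be divisible by 32")
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("synth_orchard_%d", seed))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  fruit_cols <- list(c(0.85, 0.66, 0.38), c(0.78, 0.58, 0.32),
                     c(0.90, 0.72, 0.40), c(0.72, 0.52, 0.30))
  records <- list()
  for (i in seq_len(n_images)) {
    img <- array(0, dim = c(size, size, 3))
    tex1 <- smooth_noise(size, size); tex2 <- smooth_noise(size, size)
    img[, , 1] <- 0.10 + 0.12 * tex1
    img[, , 2] <- 0.28 + 0.22 * tex2
    img[, , 3] <- 0.08 + 0.08 * tex1 * tex2
    ncl <- sample(clusters_range[1]:clusters_range[2], 1)
    boxes <- NULL
    for (k in seq_len(ncl)) {
      ccx <- stats::runif(1, 0.12, 0.88) * size
      ccy <- stats::runif(1, 0.12, 0.88) * size
      ncirc <- sample(5:20, 1)
      rad0 <- stats::runif(1, 0.022, 0.042) * size
      spread <- rad0 * stats::runif(1, 1.6, 2.6)
      col <- fruit_cols[[sample(length(fruit_cols), 1)]]
      minx <- Inf; maxx <- -Inf; miny <- Inf; maxy <- -Inf
      for (q in seq_len(ncirc)) {
        ox <- stats::rnorm(1, 0, spread); oy <- stats::rnorm(1, 0, spread * 1.3)
        rad <- rad0 * stats::runif(1, 0.7, 1.15)
        dd <- draw_disc(img, ccx + ox, ccy + oy, rad, col,
                        shade = stats::runif(1, 0.8, 1.05))
        img <- dd$img
        if (!is.null(dd$mask) && any(dd$mask$inside)) {
          hit <- which(dd$mask$inside, arr.ind = TRUE)
          miny <- min(miny, dd$mask$ys[min(hit[, 1])])
          maxy <- max(maxy, dd$mask$ys[max(hit[, 1])])
          minx <- min(minx, dd$mask$xs[min(hit[, 2])])
          maxx <- max(maxx, dd$mask$xs[max(hit[, 2])])
        }
      }
      if (!is.finite(minx)) next
      if (stats::runif(1) < occluder_prob) {
        # elongated branch stroke through the cluster
        ang <- stats::runif(1, 0, pi)
        thick <- stats::runif(1, 0.008, 0.02) * size
        len <- (maxx - minx + maxy - miny) * 1.2 + 10
        ts <- seq(-len / 2, len / 2, by = 1)
        px <- round((minx + maxx) / 2 + ts * cos(ang))
        py <- round((miny + maxy) / 2 + ts * sin(ang))
        ok <- px >= 1 & px <= size & py >= 1 & py <= size
        for (t in which(ok)) {
          xs <- max(1, px[t] - thick):min(size, px[t] + thick)
          ys <- max(1, py[t] - thick):min(size, py[t] + thick)
          img[ys, xs, 1] <- 0.25; img[ys, xs, 2] <- 0.18; img[ys, xs, 3] <- 0.10
        }
      }
      boxes <- rbind(boxes, data.frame(
        class = 0L,
        cx = (minx + maxx) / 2 / size, cy = (miny + maxy) / 2 / size,
        w = min(1, (maxx - minx + 1) / size), h = min(1, (maxy - miny + 1) / size)))
    }
    if (is.null(boxes)) {                     # extremely unlucky: retry center blob
      dd <- draw_disc(img, size / 2, size / 2, size * 0.05, fruit_cols[[1]])
      img <- dd$img
      boxes <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.11, h = 0.11)
    }
    flag <- sample(lighting_flags, 1)
    if (flag != 1) img <- brightness_adjust(img, flag)
    ipath <- file.path(dir, "images", sprintf("im%04d.png", i))
    lpath <- file.path(dir, "labels", sprintf("im%04d.txt", i))
    png::writePNG(img, ipath)
    write_labels(boxes, lpath)
    records[[i]] <- list(image = ipath, boxes = boxes, provenance = "original",
                         lighting = flag)
  }
  idx <- file.path(dir, "index.txt")
  writeLines(vapply(records, function(r) r$image, ""), idx)
  m <- manifest(records)
  m$dir <- dir
  m
}

#' Read a manifest back from an images/labels directory pair
#' @param dir directory holding `images/` and `labels/` subdirectories.
#' @return a [manifest()].
#' @export
read_manifest <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  recs <- lapply(imgs, function(ip) {
    lp <- file.path(dir, "labels",
                    sub("\\.png$", ".txt", basename(ip)))
    list(image = ip, boxes = read_labels(lp), provenance = "original")
  })
  m <- manifest(recs)
  m$dir <- dir
  m
}
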