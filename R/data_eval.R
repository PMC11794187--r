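# Dataset I/O in the plain-text detection label format (one
# "class cx cy w h" line per box, normalized center/size), the augmentation
# and split protocol, detection metrics, and scene-count accuracy.

#' Read and write plain-text detection labels
#'
#' One object per line: `class cx cy w h`, all box fields normalized to
#' `[0, 1]`. Writing uses 6 decimal places, so a write/read roundtrip is
#' lossless at that precision.
#'
#' @param path label file path.
#' @param boxes data.frame with columns `class, cx, cy, w, h`.
#' @return `read_labels`: data.frame with columns `class, cx, cy, w, h`.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  parse_line <- function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5 || anyNA(vals))
      stop(sprintf("malformed label line %d in %s: '%s'", i, path, lines[i]))
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stop(sprintf("out-of-range coordinate on line %d in %s", i, path))
    vals
  }
  m <- t(vapply(seq_along(lines), parse_line, numeric(5)))
  data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' @rdname read_labels
#' @export
write_labels <- function(boxes, path) {
  if (any(boxes[, c("cx", "cy", "w", "h")] < 0) ||
      any(boxes[, c("cx", "cy", "w", "h")] > 1))
    stop("box coordinates must lie in [0, 1]")
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   as.integer(boxes$class), boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

load_image <- function(image) {
  if (is.array(image)) return(image)
  png::readPNG(image)
}

#' Horizontal flip of an image and its boxes
#'
#' Mirrors the image left-right and maps each box center `cx` to `1 - cx`
#' (widths, heights and `cy` unchanged). An involution: applying it twice is
#' the identity.
#'
#' @param image array `(H, W, 3)` in `[0, 1]`.
#' @param boxes data.frame with `class, cx, cy, w, h`.
#' @return list with `image` and `boxes`.
#' @export
flip_lr <- function(image, boxes) {
  img <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  b <- boxes
  b$cx <- 1 - b$cx
  list(image = img, boxes = b)
}

#' Brightness adjustment by gamma mapping
#'
#' `out = in ^ flag` on unit-normalized intensities: `flag < 1` brightens
#' (highlight simulation), `flag > 1` darkens (shadow simulation). The
#' admissible range follows the augmentation table, `[0.3, 3.0]`.
#'
#' @param image array in `[0, 1]`.
#' @param flag gamma exponent in `[0.3, 3.0]`.
#' @return adjusted image, clipped to `[0, 1]`.
#' @export
brightness_adjust <- function(image, flag) {
  if (flag < 0.3 || flag > 3.0) stop("flag must lie in [0.3, 3.0]")
  pmin(pmax(image^flag, 0), 1)
}

#' Dataset manifest
#'
#' A manifest is a list of records, each holding an image (path or in-memory
#' array), its boxes, a split tag and a provenance tag
#' (`original` / `flip` / `brightness:<flag>`).
#'
#' @param records list of records.
#' @return object of class `dataset_manifest`.
#' @export
manifest <- function(records) {
  structure(list(records = records), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  nb <- sum(vapply(x$records, function(r) nrow(r$boxes), 0L))
  prov <- table(vapply(x$records, function(r) sub(":.*", "", r$provenance %||% "original"), ""))
  cat(sprintf("dataset manifest: %d images, %d boxes\n", length(x$records), nb))
  cat("  provenance:", paste(names(prov), as.integer(prov), collapse = ", "), "\n")
  invisible(x)
}

#' Number of records in a manifest
#' @param m a manifest.
#' @export
n_records <- function(m) length(m$records)

#' Augmentation specification matching the expansion protocol
#'
#' Flips plus four brightness categories (very-highlight, highlight, shadow,
#' polar-shadow) with gamma flag ranges `0.3:0.4`, `0.5:0.8`, `1.2:1.5`,
#' `2.5:3.0`. With 438 originals, one flip each and 1,584 brightness
#' variants (split as evenly as possible across the four categories) expand
#' the set to 2,460 images.
#'
#' @param n_flip number of flipped copies (at most one per original).
#' @param brightness_counts integer vector of per-category counts.
#' @return list with `n_flip` and `categories` (data.frame).
#' @export
table_augment_spec <- function(n_flip = 438L,
                               brightness_counts = c(396L, 396L, 396L, 396L)) {
  stopifnot(length(brightness_counts) == 4)
  list(n_flip = as.integer(n_flip),
       categories = data.frame(
         category = c("very_highlight", "highlight", "shadow", "polar_shadow"),
         count = as.integer(brightness_counts),
         flag_lo = c(0.3, 0.5, 1.2, 2.5),
         flag_hi = c(0.4, 0.8, 1.5, 3.0)))
}

#' Expand a dataset by flips and seeded brightness variants
#'
#' Emits `n_flip` left-right flips (one per original, in order) and, per
#' brightness category, `count` gamma variants with flags sampled uniformly
#' in the category range from seeded draws of source images (originals and
#' flips). Records are lazy: the transform is stored in the record and
#' applied by [materialize_record()]; box geometry is updated immediately.
#'
#' @param m input manifest (originals).
#' @param spec a [table_augment_spec()].
#' @param seed integer seed.
#' @return expanded manifest with `length = n + n_flip + sum(counts)`.
#' @export
augment_dataset <- function(m, spec = table_augment_spec(), seed = 0L) {
  n <- length(m$records)
  if (spec$n_flip > n)
    stop("cannot emit more flips than originals")
  set.seed(seed)
  recs <- m$records
  for (r in seq_along(recs)) recs[[r]]$provenance <- recs[[r]]$provenance %||% "original"
  out <- recs
  for (i in seq_len(spec$n_flip)) {
    r <- recs[[i]]
    b <- r$boxes; b$cx <- 1 - b$cx
    out[[length(out) + 1L]] <- list(image = r$image, boxes = b,
                                    provenance = "flip", flip = TRUE)
  }
  pool <- out                       # originals + flips are eligible sources
  for (k in seq_len(nrow(spec$categories))) {
    cat_k <- spec$categories[k, ]
    if (cat_k$count == 0) next
    src <- sample.int(length(pool), cat_k$count, replace = TRUE)
    flags <- stats::runif(cat_k$count, cat_k$flag_lo, cat_k$flag_hi)
    for (j in seq_len(cat_k$count)) {
      r <- pool[[src[j]]]
      out[[length(out) + 1L]] <- list(
        image = r$image, boxes = r$boxes,
        provenance = sprintf("brightness:%.3f", flags[j]),
        flip = isTRUE(r$flip), flag = flags[j])
    }
  }
  manifest(out)
}

#' Materialize a (possibly lazy) manifest record into an image array
#' @param r a manifest record.
#' @return array `(H, W, 3)`.
#' @export
materialize_record <- function(r) {
  img <- load_image(r$image)
  if (isTRUE(r$flip)) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (!is.null(r$flag)) img <- brightness_adjust(img, r$flag)
  img
}

#' Split a manifest into train/test or k disjoint folds
#'
#' Seeded shuffle followed by either a fraction split (default 4:1) or
#' `k_folds` equally sized disjoint folds covering every record exactly
#' once.
#'
#' @param m a manifest.
#' @param train_fraction train share (default 0.8).
#' @param k_folds if given, return k cross-validation folds instead.
#' @param seed integer seed.
#' @return for the fraction split, `list(train =, test =)`; for folds, a
#'   list of `k` manifests (the test folds).
#' @export
split_dataset <- function(m, train_fraction = 0.8, k_folds = NULL, seed = 0L) {
  n <- length(m$records)
  set.seed(seed)
  perm <- sample.int(n)
  if (!is.null(k_folds)) {
    stopifnot(n >= k_folds)
    fold_of <- rep(seq_len(k_folds), each = ceiling(n / k_folds))[seq_len(n)]
    return(lapply(seq_len(k_folds), function(k)
      manifest(m$records[perm[fold_of == k]])))
  }
  ntr <- round(n * train_fraction)
  list(train = manifest(m$records[perm[seq_len(ntr)]]),
       test = manifest(m$records[perm[(ntr + 1):n]]))
}

# ---- detection metrics ---------------------------------------------------

#' Mean average precision of detections against ground truth
#'
#' Detections are matched to ground truth greedily in descending score
#' order, one-to-one per image and class, at each IoU threshold. Average
#' precision integrates the all-point precision envelope over recall.
#' `map50` uses threshold 0.5; `map50_95` averages thresholds 0.50 to 0.95
#' in steps of 0.05. Precision and recall are reported at threshold 0.5
#' over the full detection set.
#'
#' @param dets data.frame `image, class, score, cx, cy, w, h`.
#' @param gts data.frame `image, class, cx, cy, w, h`.
#' @param iou_thresholds thresholds for the `map50_95` average.
#' @return list with `precision`, `recall`, `map50`, `map50_95`,
#'   `per_class` (AP at 0.5 per class).
#' @export
compute_map <- function(dets, gts, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(gts) == 0) {
    warning("empty ground truth; AP undefined, reported as 0")
    return(list(precision = 0, recall = 0, map50 = 0, map50_95 = 0,
                per_class = numeric(0)))
  }
  classes <- sort(unique(gts$class))
  ap_at <- function(thr) {
    vapply(classes, function(cl) {
      ap_single(dets[dets$class == cl, , drop = FALSE],
                gts[gts$class == cl, , drop = FALSE], thr)$ap
    }, 0)
  }
  ap50 <- ap_at(0.5)
  maps <- vapply(iou_thresholds, function(t) mean(ap_at(t)), 0)
  # precision / recall at 0.5 over all classes
  tp <- 0L; fp <- 0L
  for (cl in classes) {
    r <- ap_single(dets[dets$class == cl, , drop = FALSE],
                   gts[gts$class == cl, , drop = FALSE], 0.5)
    tp <- tp + r$tp; fp <- fp + r$fp
  }
  fp <- fp + sum(!dets$class %in% classes)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = tp / nrow(gts),
       map50 = mean(ap50),
       map50_95 = mean(maps),
       per_class = stats::setNames(ap50, classes))
}

# Greedy one-to-one matching for one class; returns TP/FP labels down the
# ranked list and the all-point interpolated AP.
ap_single <- function(dets, gts, thr) {
  ngt <- nrow(gts)
  if (nrow(dets) == 0) return(list(ap = 0, tp = 0L, fp = 0L))
  o <- order(-dets$score, dets$image)
  dets <- dets[o, , drop = FALSE]
  used <- new.env(parent = emptyenv())
  is_tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    gi <- which(gts$image == dets$image[i])
    if (!length(gi)) next
    iou <- box_iou_xywh(dets[i, ], gts[gi, , drop = FALSE])
    taken <- vapply(gi, function(g) isTRUE(used[[as.character(g)]]), TRUE)
    iou[taken] <- -1
    j <- which.max(iou)
    if (iou[j] >= thr) {
      used[[as.character(gi[j])]] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  rec <- tp / ngt
  prec <- tp / (tp + fp)
  # all-point interpolation: envelope of precision over recall
  env <- rev(cummax(rev(prec)))
  dr <- diff(c(0, rec))
  list(ap = sum(dr * env), tp = sum(is_tp), fp = sum(!is_tp))
}

#' Scene-count recognition accuracy
#'
#' Per-scene accuracy is correctly identified clusters over true clusters;
#' the overall accuracy pools the counts.
#'
#' @param counts data.frame with columns `scene, true, correct, wrong`.
#' @return list with `per_scene` (data.frame incl. accuracy in percent) and
#'   `overall` (percent).
#' @export
scene_accuracy <- function(counts) {
  stopifnot(all(counts$true > 0), all(counts$correct >= 0),
            all(counts$wrong >= 0), all(counts$correct <= counts$true))
  per <- counts
  per$accuracy <- 100 * counts$correct / counts$true
  list(per_scene = per, overall = 100 * sum(counts$correct) / sum(counts$true))
}
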