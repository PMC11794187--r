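# Assembly of the full detector: backbone (stem -> DenseAMA stage -> three
# C2f-Faster-AMA stages -> SPPF), PAN-FPN neck with VOVGSCSPC at every fusion
# point, and an anchor-free decoupled head with distribution-focal box
# regression. Ablation variants (baseline C2f everywhere, single swaps) are
# built by the same assembler from config flags.

#' Detector model configuration
#'
#' `widths` are the channel counts at the stem and the P2..P5 backbone
#' stages; `depths` the inner-block counts of the four backbone cross-stage
#' blocks (the neck uses depth 1). The three `use_*` flags switch the module
#' swaps on and off independently, which is how the ablation variants are
#' built. The dense-stage sizing in [dense_config()] is chosen so the full
#' model meets its parameter and compute budget; see the package vignette.
#'
#' @param num_classes number of object classes (default 1).
#' @param widths named integer vector `(stem, p2, p3, p4, p5)`.
#' @param depths integer vector of backbone C2f depths `(p2, p3, p4, p5)`.
#' @param use_dense replace the first conv + C2f pair by the DenseAMA stage.
#' @param use_faster replace the last three backbone C2f by C2f-Faster-AMA.
#' @param use_vov replace neck C2f by VOVGSCSPC.
#' @param box_loss `"inner_siou"` or one of the comparator kinds
#'   (`"ciou"`, `"diou"`, `"eiou"`, `"giou"`).
#' @param dense a [dense_config()]; `in_channels`/`out_channels` are forced
#'   to the stem and P2 widths.
#' @param siou a [siou_params()].
#' @param partial_ratio PConv ratio of the faster blocks.
#' @param reg_max number of distribution-focal bins per box edge.
#' @param strides prediction strides, increasing powers of two.
#' @param img_size default inference size (width, height), multiples of 32.
#' @return a list of class `model_config`.
#' @export
model_config <- function(num_classes = 1L,
                         widths = c(stem = 32L, p2 = 64L, p3 = 128L,
                                    p4 = 256L, p5 = 512L),
                         depths = c(1L, 2L, 2L, 1L),
                         use_dense = TRUE, use_faster = TRUE, use_vov = TRUE,
                         box_loss = "inner_siou",
                         dense = dense_config(),
                         siou = siou_params(),
                         partial_ratio = 0.25,
                         reg_max = 16L,
                         strides = c(8L, 16L, 32L),
                         img_size = c(640L, 640L)) {
  stopifnot(num_classes >= 1, length(widths) == 5, length(depths) == 4)
  if (any(diff(strides) <= 0) || any(bitwAnd(strides, strides - 1L) != 0))
    stop("strides must be strictly increasing powers of 2")
  if (any(widths[-1] %% 2 != 0)) stop("stage widths must be even")
  dense$in_channels <- as.integer(widths[[1]])
  dense$out_channels <- as.integer(widths[[2]])
  structure(list(num_classes = as.integer(num_classes),
                 widths = as.integer(widths), depths = as.integer(depths),
                 use_dense = use_dense, use_faster = use_faster,
                 use_vov = use_vov, box_loss = box_loss, dense = dense,
                 siou = siou, partial_ratio = partial_ratio,
                 reg_max = as.integer(reg_max), strides = as.integer(strides),
                 img_size = as.integer(img_size)),
            class = "model_config")
}

#' Preset configurations
#'
#' `baseline_config()` is the unmodified s-scale detector (standard C2f
#' backbone and neck, CIoU box loss); `longan_config()` enables all three
#' module swaps and the Inner-SIoU loss; `nano_config()` is a width /8
#' miniature of the full model for fast CPU experiments and smoke training.
#'
#' @param num_classes number of classes.
#' @param ... passed on to [model_config()].
#' @return a `model_config`.
#' @export
baseline_config <- function(num_classes = 1L, ...) {
  model_config(num_classes, use_dense = FALSE, use_faster = FALSE,
               use_vov = FALSE, box_loss = "ciou", ...)
}

#' @rdname baseline_config
#' @export
longan_config <- function(num_classes = 1L, ...) {
  model_config(num_classes, ...)
}

#' @rdname baseline_config
#' @export
nano_config <- function(num_classes = 1L, ...) {
  model_config(num_classes,
               widths = c(stem = 4L, p2 = 8L, p3 = 16L, p4 = 32L, p5 = 64L),
               dense = dense_config(growth_rate = 4L, num_layers = 2L,
                                    bottleneck_factor = 2L),
               img_size = c(160L, 160L), ...)
}

#' Build the detector from a configuration
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling weight initialization.
#' @return a module of class `detector`.
#' @export
build_model <- function(cfg = longan_config(), seed = 0L) {
  set.seed(seed)
  w <- cfg$widths; d <- cfg$depths
  nc <- cfg$num_classes; rm4 <- 4L * cfg$reg_max
  mk_c2f <- function(cin, cout, n, shortcut) {
    if (cfg$use_faster) c2f_faster_ama(cin, cout, n, cfg$partial_ratio)
    else c2f(cin, cout, n, shortcut)
  }
  mk_fuse <- function(cin, cout) {
    if (cfg$use_vov) vovgscspc(cin, cout) else c2f(cin, cout, 1L, FALSE)
  }
  stem <- conv_bn_act(3L, w[1], 3L, 2L)                      # P1/2
  stage2 <- if (cfg$use_dense) dense_ama_stage(cfg$dense)    # P2/4
            else new_module("conv_c2f",
                            cv = conv_bn_act(w[1], w[2], 3L, 2L),
                            c2f = c2f(w[2], w[2], d[1], TRUE))
  backbone <- list(
    stem = stem,
    stage2 = stage2,
    conv3 = conv_bn_act(w[2], w[3], 3L, 2L),                 # P3/8
    block3 = mk_c2f(w[3], w[3], d[2], TRUE),
    conv4 = conv_bn_act(w[3], w[4], 3L, 2L),                 # P4/16
    block4 = mk_c2f(w[4], w[4], d[3], TRUE),
    conv5 = conv_bn_act(w[4], w[5], 3L, 2L),                 # P5/32
    block5 = mk_c2f(w[5], w[5], d[4], TRUE),
    sppf = sppf(w[5]))
  neck <- list(
    fuse_p4 = mk_fuse(w[5] + w[4], w[4]),
    fuse_p3 = mk_fuse(w[4] + w[3], w[3]),
    down_p3 = conv_bn_act(w[3], w[3], 3L, 2L),
    fuse_p4b = mk_fuse(w[3] + w[4], w[4]),
    down_p4 = conv_bn_act(w[4], w[4], 3L, 2L),
    fuse_p5b = mk_fuse(w[4] + w[5], w[5]))
  c2h <- max(16L, w[3] %/% 4L, rm4)
  c3h <- max(w[3], min(nc, 100L))
  mk_head <- function(ci) list(
    reg = list(conv_bn_act(ci, c2h, 3L), conv_bn_act(c2h, c2h, 3L),
               conv_plain(c2h, rm4, 1L)),
    cls = list(conv_bn_act(ci, c3h, 3L), conv_bn_act(c3h, c3h, 3L),
               conv_plain(c3h, nc, 1L)))
  head <- lapply(c(w[3], w[4], w[5]), mk_head)
  # classification prior: start detections rare, box bins mildly positive
  for (h in head) {
    h$cls[[3]]$b$value[] <- log(0.01 / 0.99)
    h$reg[[3]]$b$value[] <- 1
  }
  new_module("detector", backbone = backbone, neck = neck, head = head,
             cfg = cfg)
}

#' @export
forward.conv_c2f <- function(m, x, ...) forward(m$c2f, forward(m$cv, x))

run_seq <- function(mods, x) { for (m in mods) x <- forward(m, x); x }

# Full forward: returns per-scale raw head outputs.
#' @export
forward.detector <- function(m, x, ...) {
  b <- m$backbone
  x <- forward(b$stem, x)
  x <- forward(b$stage2, x)
  p3 <- forward(b$block3, forward(b$conv3, x))
  p4 <- forward(b$block4, forward(b$conv4, p3))
  p5 <- forward(b$sppf, forward(b$block5, forward(b$conv5, p4)))
  n <- m$neck
  f1 <- forward(n$fuse_p4, op_concat_c(list(op_upsample2(p5), p4)))
  f2 <- forward(n$fuse_p3, op_concat_c(list(op_upsample2(f1), p3)))   # P3 out
  f3 <- forward(n$fuse_p4b, op_concat_c(list(forward(n$down_p3, f2), f1)))
  f4 <- forward(n$fuse_p5b, op_concat_c(list(forward(n$down_p4, f3), p5)))
  feats <- list(f2, f3, f4)
  lapply(seq_along(feats), function(i) {
    h <- m$head[[i]]
    list(reg = run_seq(h$reg, feats[[i]]), cls = run_seq(h$cls, feats[[i]]))
  })
}

#' Parameter accounting
#'
#' Exact trainable-parameter counts per named sub-module and in total.
#'
#' @param model a built detector (or any module).
#' @return a list of class `param_report` with `per_module` and `total`.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "detector")) {
    groups <- c(
      lapply(model$backbone, n_parameters),
      lapply(model$neck, n_parameters),
      list(head = sum(vapply(model$head, n_parameters, 0))))
    names(groups)[seq_along(model$backbone)] <- names(model$backbone)
    per <- unlist(groups)
  } else {
    per <- c(total = n_parameters(model))
  }
  structure(list(per_module = per, total = sum(per)), class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat("parameters by module:\n")
  for (nm in names(x$per_module))
    cat(sprintf("  %-10s %10d\n", nm, x$per_module[[nm]]))
  cat(sprintf("  total      %10d  (%.1f M)\n", x$total, x$total / 1e6))
  invisible(x)
}

#' Analytic FLOP count at a given input size
#'
#' Runs one forward pass on a zero image with a FLOP meter armed: every
#' convolution and linear map adds `2 x` its multiply-accumulate count;
#' normalization, pooling and activations count zero, the convention used
#' when detector compute budgets are printed in GFLOPs.
#'
#' @param model a built detector.
#' @param input_size `c(width, height)`, multiples of 32.
#' @return GFLOPs (numeric).
#' @export
count_flops <- function(model, input_size = model$cfg$img_size) {
  stopifnot(all(input_size %% 32 == 0))
  x <- array(0, dim = c(input_size[2], input_size[1], 1L, 3L))
  ag_set_training(FALSE)
  ag_no_grad({
    ag_flops_start()
    forward(model, x)
    fl <- ag_flops_stop()
  })
  fl / 1e9
}

# ---- decoding and NMS ----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Decode raw per-scale outputs into normalized center/size boxes + scores.
# Returns a data.frame per image index.
decode_outputs <- function(model, outs, img_w, img_h) {
  cfg <- model$cfg
  rm_ <- cfg$reg_max
  bins <- 0:(rm_ - 1L)
  rows <- list()
  for (i in seq_along(outs)) {
    reg <- ag_value(outs[[i]]$reg); cls <- ag_value(outs[[i]]$cls)
    dm <- dim(reg); gh <- dm[1]; gw <- dm[2]; n <- dm[3]
    s <- cfg$strides[i]
    nc <- cfg$num_classes
    ncell <- gh * gw * n
    regm <- reg; dim(regm) <- c(ncell, 4L * rm_)
    clsm <- cls; dim(clsm) <- c(ncell, nc)
    # cell centers in pixels; row index order is (h, w, n), h fastest
    cyc <- (rep.int(seq_len(gh), gw * n) - 0.5) * s
    cxc <- (rep.int(rep(seq_len(gw), each = gh), n) - 0.5) * s
    imgi <- rep(seq_len(n), each = gh * gw)
    dists <- matrix(0, ncell, 4L)
    for (e in 1:4) {
      p <- softmax_rows(regm[, ((e - 1L) * rm_ + 1L):(e * rm_), drop = FALSE])
      dists[, e] <- as.vector(p %*% bins)
    }
    x1 <- cxc - dists[, 1] * s; y1 <- cyc - dists[, 2] * s
    x2 <- cxc + dists[, 3] * s; y2 <- cyc + dists[, 4] * s
    score <- 1 / (1 + exp(-clsm))
    best_cls <- max.col(score, ties.method = "first")
    best_score <- score[cbind(seq_len(ncell), best_cls)]
    rows[[i]] <- data.frame(
      image = imgi, scale = i,
      cx = (x1 + x2) / 2 / img_w, cy = (y1 + y2) / 2 / img_h,
      w = (x2 - x1) / img_w, h = (y2 - y1) / img_h,
      score = best_score, class = best_cls - 1L)
  }
  do.call(rbind, rows)
}

box_iou_xywh <- function(a, b) {
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  uni <- a$w * a$h + b$w * b$h - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Greedy non-maximum suppression
#'
#' Score-descending greedy suppression: a box is kept unless it overlaps an
#' already-kept box of the same class with IoU above `iou_thresh`. Exact
#' duplicates therefore collapse to one survivor.
#'
#' @param dets data.frame with columns `cx, cy, w, h, score, class`.
#' @param iou_thresh suppression threshold.
#' @return the kept subset, ordered by decreasing score.
#' @export
nms_boxes <- function(dets, iou_thresh = 0.45) {
  if (nrow(dets) == 0) return(dets)
  dets <- dets[order(-dets$score), , drop = FALSE]
  keep <- logical(nrow(dets))
  for (cl in unique(dets$class)) {
    idx <- which(dets$class == cl)
    live <- rep(TRUE, length(idx))
    for (a in seq_along(idx)) {
      if (!live[a]) next
      keep[idx[a]] <- TRUE
      if (a < length(idx)) {
        rest <- idx[(a + 1):length(idx)][live[(a + 1):length(idx)]]
        if (length(rest)) {
          iou <- box_iou_xywh(dets[idx[a], ], dets[rest, ])
          live[match(rest[iou > iou_thresh], idx)] <- FALSE
        }
      }
    }
  }
  dets[keep, , drop = FALSE]
}

#' Run inference and post-processing
#'
#' Forward pass in evaluation mode, distribution-focal decoding, confidence
#' filtering and class-wise NMS. Boxes are returned in normalized
#' center/size form.
#'
#' @param model a built detector.
#' @param images array `(H, W, N, 3)` or a list of `(H, W, 3)` arrays, pixel
#'   values in `[0, 1]`; H and W must be divisible by 32.
#' @param conf_thresh confidence threshold (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @param use_batch_stats use batch statistics in the normalization layers
#'   (for evaluating on the training batch itself).
#' @return data.frame of detections with an `image` index column.
#' @export
forward_predict <- function(model, images, conf_thresh = 0.25, nms_iou = 0.45,
                            use_batch_stats = FALSE) {
  x <- images_to_batch(images)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) stop("image size must be divisible by 32")
  ag_set_training(isTRUE(use_batch_stats))
  on.exit(ag_set_training(FALSE))
  dets <- ag_no_grad({
    outs <- forward(model, x)
    decode_outputs(model, outs, d[2], d[1])
  })
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  out <- lapply(split(dets, dets$image), nms_boxes, iou_thresh = nms_iou)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$image, -res$score), , drop = FALSE]
}

images_to_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], length(images), d[3]))
  for (i in seq_along(images)) x[, , i, ] <- images[[i]]
  x
}

# ---- config and weight serialization ------------------------------------

#' Read / write a model configuration as YAML
#'
#' The YAML mirrors the [model_config()] fields; nested `dense` and `siou`
#' blocks map to [dense_config()] and [siou_params()].
#'
#' @param path YAML file path.
#' @param cfg a `model_config`.
#' @return `read_model_config`: a `model_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  dn <- do.call(dense_config, y$dense %||% list())
  si <- do.call(siou_params, y$siou %||% list())
  y$dense <- dn; y$siou <- si
  y$widths <- unlist(y$widths)
  do.call(model_config, y)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$dense <- unclass(out$dense)
  out$siou <- unclass(out$siou)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Save / load detector weights
#'
#' Serializes every trainable tensor plus the normalization running
#' statistics into R's native serialization format; `load_weights` restores
#' them into a freshly built model of the same configuration.
#'
#' @param model a built detector.
#' @param path file path (conventionally `.rds`).
#' @return `load_weights` returns the model, invisibly.
#' @export
save_weights <- function(model, path) {
  params <- module_params(model)
  vals <- lapply(params, function(p) p$value)
  bns <- collect_bn_states(model)
  saveRDS(list(cfg = model$cfg, params = vals,
               bn = lapply(bns, function(st)
                 list(mean = st$running_mean, var = st$running_var))), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  blob <- readRDS(path)
  params <- module_params(model)
  stopifnot(identical(names(params), names(blob$params)))
  for (nm in names(params)) params[[nm]]$value <- blob$params[[nm]]
  bns <- collect_bn_states(model)
  stopifnot(length(bns) == length(blob$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- blob$bn[[i]]$mean
    bns[[i]]$running_var <- blob$bn[[i]]$var
  }
  invisible(model)
}

collect_bn_states <- function(m) {
  out <- list()
  walk <- function(obj) {
    if (is.environment(obj) && !is.null(obj$running_mean)) {
      out[[length(out) + 1L]] <<- obj
      return(invisible(NULL))
    }
    if (is.list(obj)) for (el in obj) walk(el)
    invisible(NULL)
  }
  walk(unclass(m))
  out
}
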