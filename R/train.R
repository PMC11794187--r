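# Training: a center-inside target assigner, the composite detection loss
# (Inner-SIoU box term + binary cross-entropy classification + distribution-
# focal regression), and a seeded optimization loop. The loss and its
# gradient with respect to the raw head outputs are computed in closed form
# and injected into the autodiff tape as a single node, which keeps the
# per-cell bookkeeping out of the tape.

# Assign ground-truth boxes to prediction cells: a cell is a candidate for a
# GT if its center lies inside the GT box; each candidate takes the GT with
# the nearest center; cells whose required edge distance exceeds the
# distribution range are dropped.
assign_targets <- function(cfg, gts_px, grid, img_w, img_h) {
  rm_ <- cfg$reg_max
  out <- list()
  for (i in seq_along(cfg$strides)) {
    s <- cfg$strides[i]
    gh <- grid[[i]][1]; gw <- grid[[i]][2]
    cyc <- (rep.int(seq_len(gh), gw) - 0.5) * s
    cxc <- (rep(seq_len(gw), each = gh) - 0.5) * s
    res <- list()
    for (n in seq_along(gts_px)) {
      g <- gts_px[[n]]
      if (is.null(g) || nrow(g) == 0) { res[n] <- list(NULL); next }
      x1 <- g$cx - g$w / 2; x2 <- g$cx + g$w / 2
      y1 <- g$cy - g$h / 2; y2 <- g$cy + g$h / 2
      cand_gt <- integer(0); cand_cell <- integer(0)
      for (k in seq_len(nrow(g))) {
        inside <- which(cxc > x1[k] & cxc < x2[k] & cyc > y1[k] & cyc < y2[k])
        # edge distances in stride units must be representable
        if (length(inside)) {
          dl <- (cxc[inside] - x1[k]) / s; dr <- (x2[k] - cxc[inside]) / s
          dt <- (cyc[inside] - y1[k]) / s; db <- (y2[k] - cyc[inside]) / s
          ok <- pmax(dl, dr, dt, db) < rm_ - 1e-3
          inside <- inside[ok]
        }
        if (length(inside)) {
          cand_gt <- c(cand_gt, rep(k, length(inside)))
          cand_cell <- c(cand_cell, inside)
        }
      }
      if (!length(cand_cell)) { res[n] <- list(NULL); next }
      d2 <- (cxc[cand_cell] - g$cx[cand_gt])^2 + (cyc[cand_cell] - g$cy[cand_gt])^2
      o <- order(cand_cell, d2)
      first <- !duplicated(cand_cell[o])
      res[[n]] <- data.frame(cell = cand_cell[o][first], gt = cand_gt[o][first])
    }
    out[[i]] <- res
  }
  out
}

# Composite loss and gradient for one scale. reg/cls are raw value arrays;
# returns loss pieces and gradient arrays of the same shapes.
scale_loss <- function(cfg, reg, cls, assign, gts_px, img_w, img_h, i,
                       gains = c(box = 7.5, cls = 0.5, dfl = 1.5)) {
  rm_ <- cfg$reg_max; bins <- 0:(rm_ - 1L)
  s <- cfg$strides[i]
  dm <- dim(reg); gh <- dm[1]; gw <- dm[2]; n <- dm[3]
  ncell <- gh * gw
  regm <- reg; dim(regm) <- c(ncell * n, 4L * rm_)
  clsm <- cls; dim(clsm) <- c(ncell * n, cfg$num_classes)
  tgt <- matrix(0, ncell * n, cfg$num_classes)
  dreg <- matrix(0, ncell * n, 4L * rm_)
  cyc <- (rep.int(seq_len(gh), gw) - 0.5) * s
  cxc <- (rep(seq_len(gw), each = gh) - 0.5) * s
  box_loss <- 0; dfl_loss <- 0; npos <- 0L
  for (nn in seq_len(n)) {
    a <- assign[[i]][[nn]]
    if (is.null(a) || nrow(a) == 0) next
    g <- gts_px[[nn]]
    rows <- (nn - 1L) * ncell + a$cell
    tgt[cbind(rows, g$class[a$gt] + 1L)] <- 1
    npos <- npos + nrow(a)
    for (j in seq_len(nrow(a))) {
      r <- rows[j]; k <- a$gt[j]
      ax <- cxc[a$cell[j]]; ay <- cyc[a$cell[j]]
      z <- matrix(regm[r, ], rm_, 4L)          # bins x edges
      p <- apply(z, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
      d <- as.vector(bins %*% p)               # l, t, r, b in stride units
      # decoded normalized box
      x1 <- ax - d[1] * s; y1 <- ay - d[2] * s
      x2 <- ax + d[3] * s; y2 <- ay + d[4] * s
      pb <- c((x1 + x2) / 2 / img_w, (y1 + y2) / 2 / img_h,
              (x2 - x1) / img_w, (y2 - y1) / img_h)
      gb <- c(g$cx[k] / img_w, g$cy[k] / img_h, g$w[k] / img_w, g$h[k] / img_h)
      if (cfg$box_loss == "inner_siou") {
        box_loss <- box_loss + inner_siou_loss(pb, gb, cfg$siou)$total
        gbox <- inner_siou_grad(pb, gb, cfg$siou)
      } else {
        box_loss <- box_loss + iou_family(pb, gb, cfg$box_loss)
        gbox <- numeric(4)                      # central differences
        for (q in 1:4) {
          hp <- pb; hp[q] <- hp[q] + 1e-6
          hm <- pb; hm[q] <- hm[q] - 1e-6
          gbox[q] <- (iou_family(hp, gb, cfg$box_loss) -
                      iou_family(hm, gb, cfg$box_loss)) / 2e-6
        }
      }
      # chain the box-loss gradient to (l,t,r,b) in stride units
      gl <- numeric(4)
      gl[1] <- gbox[1] * (-s / (2 * img_w)) + gbox[3] * (s / img_w)
      gl[2] <- gbox[2] * (-s / (2 * img_h)) + gbox[4] * (s / img_h)
      gl[3] <- gbox[1] * (s / (2 * img_w)) + gbox[3] * (s / img_w)
      gl[4] <- gbox[2] * (s / (2 * img_h)) + gbox[4] * (s / img_h)
      # distribution-focal term on the same logits
      tl <- pmin(floor(d_target <- pmin(pmax(c(
        (ax - (g$cx[k] - g$w[k] / 2)) / s,
        (ay - (g$cy[k] - g$h[k] / 2)) / s,
        ((g$cx[k] + g$w[k] / 2) - ax) / s,
        ((g$cy[k] + g$h[k] / 2) - ay) / s), 0), rm_ - 1 - 1e-3)), rm_ - 2)
      wr <- d_target - tl; wl <- 1 - wr
      for (e in 1:4) {
        pe <- p[, e]
        dfl_loss <- dfl_loss - (wl[e] * log(max(pe[tl[e] + 1], 1e-12)) +
                                wr[e] * log(max(pe[tl[e] + 2], 1e-12)))
        tvec <- numeric(rm_)
        tvec[tl[e] + 1] <- wl[e]; tvec[tl[e] + 2] <- wr[e]
        # grad through softmax for DFL (CE) and expectation (box)
        ce_grad <- pe - tvec
        exp_grad <- gl[e] * pe * (bins - d[e])
        cols <- ((e - 1L) * rm_ + 1L):(e * rm_)
        dreg[r, cols] <- dreg[r, cols] + gains["dfl"] * ce_grad + gains["box"] * exp_grad
      }
    }
  }
  npos_tot <- max(1L, npos)
  sig <- 1 / (1 + exp(-clsm))
  cls_loss <- -sum(tgt * log(pmax(sig, 1e-12)) +
                   (1 - tgt) * log(pmax(1 - sig, 1e-12)))
  dcls <- gains["cls"] * (sig - tgt)
  list(box = box_loss, cls = cls_loss, dfl = dfl_loss, npos = npos,
       dreg = dreg, dcls = dcls)
}

#' Train a detector on a dataset manifest
#'
#' Full-batch seeded training with the composite detection loss: the
#' configured box-overlap loss (Inner-SIoU by default) on decoded boxes,
#' binary cross-entropy on the classification logits, and the
#' distribution-focal term on the box-bin logits (gains 7.5 / 0.5 / 1.5).
#' Targets come from a center-inside assigner: every prediction cell whose
#' center falls inside a ground-truth box (and whose required edge distances
#' are representable by the bin range) is a positive for the nearest such
#' box. The learning rate anneals linearly from `lr0` to `lr0 * lrf`.
#'
#' @param model a built detector.
#' @param manifest a dataset manifest (see [synth_orchard()] /
#'   [read_manifest()]) whose images share one size divisible by 32.
#' @param hyp list of hyperparameters: `steps` (200), `lr0` (0.01), `lrf`
#'   (0.01), `optimizer` (`"adam"` or `"sgd"`), `momentum` (0.937),
#'   `warmup` (fraction of steps with linearly ramped learning rate).
#' @param seed integer seed (shuffling and any stochastic parts).
#' @param verbose print loss every 20 steps.
#' @return list with `model` (trained, same object) and `history`
#'   (data.frame of loss components per step).
#' @export
train_detector <- function(model, manifest, hyp = list(), seed = 0L,
                           verbose = FALSE) {
  if (length(manifest$records) == 0) stop("empty dataset")
  h <- utils::modifyList(list(steps = 200L, lr0 = 0.01, lrf = 0.01,
                              optimizer = "adam", momentum = 0.937,
                              warmup = 0.1), hyp)
  set.seed(seed)
  cfg <- model$cfg
  imgs <- lapply(manifest$records, function(r) load_image(r$image))
  x <- images_to_batch(imgs)
  d <- dim(x); img_h <- d[1]; img_w <- d[2]
  gts_px <- lapply(manifest$records, function(r) {
    b <- r$boxes
    data.frame(class = b$class, cx = b$cx * img_w, cy = b$cy * img_h,
               w = b$w * img_w, h = b$h * img_h)
  })
  grid <- lapply(cfg$strides, function(s) c(img_h %/% s, img_w %/% s))
  assign <- assign_targets(cfg, gts_px, grid, img_w, img_h)
  params <- module_params(model)
  opt <- lapply(params, function(p) list(m = 0 * p$value, v = 0 * p$value))
  hist <- data.frame(step = integer(0), box = numeric(0), cls = numeric(0),
                     dfl = numeric(0), total = numeric(0))
  for (step in seq_len(h$steps)) {
    ag_set_training(TRUE)
    outs <- forward(model, x)
    pieces <- lapply(seq_along(outs), function(i) {
      scale_loss(cfg, ag_value(outs[[i]]$reg), ag_value(outs[[i]]$cls),
                 assign, gts_px, img_w, img_h, i)
    })
    npos <- max(1L, sum(vapply(pieces, function(p) p$npos, 0L)))
    box_l <- sum(vapply(pieces, function(p) p$box, 0)) / npos
    cls_l <- sum(vapply(pieces, function(p) p$cls, 0)) / npos
    dfl_l <- sum(vapply(pieces, function(p) p$dfl, 0)) / (4 * npos)
    total <- 7.5 * box_l + 0.5 * cls_l + 1.5 * dfl_l
    if (!is.finite(total)) stop("non-finite loss at step ", step,
                                " (box ", box_l, ", cls ", cls_l,
                                ", dfl ", dfl_l, ")")
    parents <- list(); grads <- list()
    for (i in seq_along(outs)) {
      pr <- pieces[[i]]$dreg / npos
      dim(pr) <- dim(ag_value(outs[[i]]$reg))
      pc <- pieces[[i]]$dcls / npos
      dim(pc) <- dim(ag_value(outs[[i]]$cls))
      parents <- c(parents, list(outs[[i]]$reg, outs[[i]]$cls))
      grads <- c(grads, list(pr, pc))
    }
    loss_node <- ag_node(total, parents,
                         function(g) lapply(grads, function(G) G * as.numeric(g)))
    ag_backward(loss_node)
    frac <- step / h$steps
    lr <- h$lr0 * (1 - frac) + h$lr0 * h$lrf * frac
    if (h$warmup > 0 && frac < h$warmup) lr <- lr * frac / h$warmup
    for (k in seq_along(params)) {
      p <- params[[k]]
      if (is.null(p$grad)) next
      if (h$optimizer == "adam") {
        st <- opt[[k]]
        st$m <- 0.9 * st$m + 0.1 * p$grad
        st$v <- 0.999 * st$v + 0.001 * p$grad^2
        mh <- st$m / (1 - 0.9^step); vh <- st$v / (1 - 0.999^step)
        p$value <- p$value - lr * mh / (sqrt(vh) + 1e-8)
        opt[[k]] <- st
      } else {
        st <- opt[[k]]
        st$m <- h$momentum * st$m + p$grad
        p$value <- p$value - lr * st$m
        opt[[k]] <- st
      }
      p$grad <- NULL
    }
    hist <- rbind(hist, data.frame(step = step, box = box_l, cls = cls_l,
                                   dfl = dfl_l, total = total))
    if (verbose && step %% 20 == 0)
      message(sprintf("step %3d  box %.4f  cls %.4f  dfl %.4f  total %.4f",
                      step, box_l, cls_l, dfl_l, total))
  }
  ag_set_training(FALSE)
  list(model = model, history = hist)
}
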