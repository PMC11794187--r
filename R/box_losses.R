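# Inner-SIoU bounding-box regression loss: auxiliary inner boxes scaled about
# the box centers, inner IoU, and the angle / distance / shape penalties,
# plus the CIoU / DIoU / EIoU / GIoU comparator losses. Analytic gradients
# with respect to the predicted box are provided for training and are checked
# against central differences in the test suite.

#' Box constructor (center / size form)
#' @param cx,cy center coordinates.
#' @param w,h non-negative width and height.
#' @return numeric vector `c(cx, cy, w, h)` of class `box`.
#' @export
box <- function(cx, cy, w, h) {
  stopifnot(w >= 0, h >= 0)
  structure(c(cx = cx, cy = cy, w = w, h = h), class = "box")
}

#' Parameters of the Inner-SIoU loss
#'
#' @param ratio inner-box scale factor in `[0.5, 1.5]`; 1 reduces the inner
#'   IoU to the plain IoU.
#' @param theta shape-cost exponent (>= 1), default 4.
#' @param eps degeneracy tolerance.
#' @return list of class `siou_params`.
#' @export
siou_params <- function(ratio = 1.0, theta = 4, eps = 1e-9) {
  if (ratio < 0.5 || ratio > 1.5) stop("ratio must lie in [0.5, 1.5]")
  stopifnot(theta >= 1)
  structure(list(ratio = ratio, theta = theta, eps = eps), class = "siou_params")
}

#' Auxiliary inner box
#'
#' Scales a box about its center by `ratio` and returns its corners.
#'
#' @param b a [box()] (or numeric `c(cx, cy, w, h)`).
#' @param ratio scale factor in `[0.5, 1.5]`.
#' @return list with edges `l`, `r`, `t`, `b`.
#' @examples
#' inner_box(box(0.5, 0.5, 0.4, 0.2), ratio = 0.5)
#' @export
inner_box <- function(b, ratio = 1.0) {
  if (ratio < 0.5 || ratio > 1.5) stop("ratio must lie in [0.5, 1.5]")
  list(l = b[[1]] - b[[3]] * ratio / 2, r = b[[1]] + b[[3]] * ratio / 2,
       t = b[[2]] - b[[4]] * ratio / 2, b = b[[2]] + b[[4]] * ratio / 2)
}

#' Inner IoU of two boxes
#'
#' IoU of the auxiliary boxes obtained by scaling both boxes about their
#' centers by `ratio`; negative overlaps are clamped to zero and a zero
#' union returns 0. `ratio = 1` reproduces the standard IoU exactly.
#'
#' @param b,bgt predicted and ground-truth [box()]es.
#' @param ratio inner-box scale factor.
#' @return IoU in `[0, 1]`.
#' @export
inner_iou <- function(b, bgt, ratio = 1.0) {
  A <- inner_box(b, ratio); G <- inner_box(bgt, ratio)
  iw <- max(0, min(A$r, G$r) - max(A$l, G$l))
  ih <- max(0, min(A$b, G$b) - max(A$t, G$t))
  inter <- iw * ih
  uni <- b[[3]] * b[[4]] * ratio^2 + bgt[[3]] * bgt[[4]] * ratio^2 - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Angle cost of the SIoU family
#'
#' With center distance `sigma` and vertical center gap `c_h`, sets
#' `x = c_h / sigma` (clamped to `[0, 1]`) and returns
#' `1 - 2 sin^2(asin(x) - pi/4)`, equivalently `sin(2 asin x)`: zero when the
#' centers are horizontally or vertically aligned, one at 45 degrees.
#' Coincident centers return 0 by convention.
#'
#' @param b,bgt predicted and ground-truth boxes.
#' @param eps degeneracy tolerance for the center distance.
#' @return angle cost in `[0, 1]`.
#' @export
angle_cost <- function(b, bgt, eps = 1e-9) {
  dx <- bgt[[1]] - b[[1]]; dy <- bgt[[2]] - b[[2]]
  sigma <- sqrt(dx^2 + dy^2)
  if (sigma < eps) return(0)
  x <- min(max(abs(dy) / sigma, 0), 1)
  1 - 2 * sin(asin(x) - pi / 4)^2
}

enclose_extent <- function(b, bgt) {
  list(cw = max(b[[1]] + b[[3]] / 2, bgt[[1]] + bgt[[3]] / 2) -
            min(b[[1]] - b[[3]] / 2, bgt[[1]] - bgt[[3]] / 2),
       ch = max(b[[2]] + b[[4]] / 2, bgt[[2]] + bgt[[4]] / 2) -
            min(b[[2]] - b[[4]] / 2, bgt[[2]] - bgt[[4]] / 2))
}

#' Distance cost of the SIoU family
#'
#' Normalizes the center offsets by the width/height of the smallest
#' axis-aligned box enclosing both boxes, and accumulates
#' `1 - exp(-gamma * rho_t)` per axis with `gamma = 2 - angle`. A zero
#' enclosing extent in a dimension contributes 0.
#'
#' @param b,bgt predicted and ground-truth boxes.
#' @param angle the [angle_cost()] of the pair.
#' @return distance cost, non-negative.
#' @export
distance_cost <- function(b, bgt, angle = angle_cost(b, bgt)) {
  e <- enclose_extent(b, bgt)
  gam <- 2 - angle
  out <- 0
  if (e$cw > 0) out <- out + 1 - exp(-gam * ((bgt[[1]] - b[[1]]) / e$cw)^2)
  if (e$ch > 0) out <- out + 1 - exp(-gam * ((bgt[[2]] - b[[2]]) / e$ch)^2)
  out
}

#' Shape cost of the SIoU family
#'
#' Relative width/height mismatches `|w - w_gt| / max(w, w_gt)` are mapped
#' through `(1 - exp(-omega))^theta` and summed; bounded by
#' `2 * (1 - exp(-1))^theta`. A dimension degenerate in both boxes
#' contributes 0.
#'
#' @param b,bgt predicted and ground-truth boxes.
#' @param theta shape exponent.
#' @return shape cost, non-negative.
#' @export
shape_cost <- function(b, bgt, theta = 4) {
  out <- 0
  mw <- max(b[[3]], bgt[[3]])
  if (mw > 0) out <- out + (1 - exp(-abs(b[[3]] - bgt[[3]]) / mw))^theta
  mh <- max(b[[4]], bgt[[4]])
  if (mh > 0) out <- out + (1 - exp(-abs(b[[4]] - bgt[[4]]) / mh))^theta
  out
}

#' Inner-SIoU loss with component breakdown
#'
#' `total = 1 - inner_iou + (distance + shape) / 2`, where the distance cost
#' is modulated by the angle cost. Identical boxes give 0.
#'
#' @param b,bgt predicted and ground-truth [box()]es.
#' @param params a [siou_params()].
#' @return list with `iou_inner`, `angle`, `distance`, `shape`, `total`.
#' @export
inner_siou_loss <- function(b, bgt, params = siou_params()) {
  iou <- inner_iou(b, bgt, params$ratio)
  ang <- angle_cost(b, bgt, params$eps)
  dis <- distance_cost(b, bgt, ang)
  shp <- shape_cost(b, bgt, params$theta)
  list(iou_inner = iou, angle = ang, distance = dis, shape = shp,
       total = 1 - iou + (dis + shp) / 2)
}

#' Analytic gradient of the Inner-SIoU loss
#'
#' Gradient of `inner_siou_loss(...)$total` with respect to the predicted box
#' `(cx, cy, w, h)`. At kinks of the min/max/abs terms a one-sided
#' subgradient is returned; the clamp of the angle argument near 1 is
#' handled by capping it just below 1.
#'
#' @inheritParams inner_siou_loss
#' @return numeric length-4 gradient `d total / d (cx, cy, w, h)`.
#' @export
inner_siou_grad <- function(b, bgt, params = siou_params()) {
  r <- params$ratio; eps <- params$eps
  cx <- b[[1]]; cy <- b[[2]]; w <- b[[3]]; h <- b[[4]]
  gx <- bgt[[1]]; gy <- bgt[[2]]; gw <- bgt[[3]]; gh <- bgt[[4]]
  g <- numeric(4)

  # ---- inner IoU term ----
  A <- inner_box(b, r); G <- inner_box(bgt, r)
  iw <- min(A$r, G$r) - max(A$l, G$l)
  ih <- min(A$b, G$b) - max(A$t, G$t)
  inter <- max(0, iw) * max(0, ih)
  uni <- w * h * r^2 + gw * gh * r^2 - inter
  if (uni > 0) {
    # d inter
    d_iw <- c(0, 0, 0, 0); d_ih <- c(0, 0, 0, 0)
    if (iw > 0 && ih > 0) {
      sel_min_x <- as.numeric(A$r <= G$r)   # pred right edge active in min
      sel_max_x <- as.numeric(A$l >= G$l)   # pred left edge active in max
      d_iw <- c(sel_min_x - sel_max_x, 0, (sel_min_x + sel_max_x) * r / 2, 0)
      sel_min_y <- as.numeric(A$b <= G$b)
      sel_max_y <- as.numeric(A$t >= G$t)
      d_ih <- c(0, sel_min_y - sel_max_y, 0, (sel_min_y + sel_max_y) * r / 2)
    }
    d_inter <- if (iw > 0 && ih > 0) ih * d_iw + iw * d_ih else c(0, 0, 0, 0)
    d_area <- c(0, 0, h * r^2, w * r^2)
    d_uni <- d_area - d_inter
    d_iou <- (d_inter * uni - inter * d_uni) / uni^2
    g <- g - d_iou
  }

  # ---- angle cost and its gradient (wrt cx, cy only) ----
  dx <- gx - cx; dy <- gy - cy
  sigma <- sqrt(dx^2 + dy^2)
  ang <- 0; d_ang <- c(0, 0, 0, 0)
  if (sigma >= eps) {
    x <- min(max(abs(dy) / sigma, 0), 1)
    ang <- 1 - 2 * sin(asin(x) - pi / 4)^2
    xg <- min(x, 1 - 1e-7)
    dang_dx <- 2 * (1 - 2 * xg^2) / sqrt(1 - xg^2)
    sgn <- if (dy > 0) 1 else if (dy < 0) -1 else 0
    dx_dDx <- -abs(dy) * dx / sigma^3
    dx_dDy <- sgn * dx^2 / sigma^3
    # d(Delta_x)/d cx = -1, d(Delta_y)/d cy = -1
    d_ang <- c(-dang_dx * dx_dDx, -dang_dx * dx_dDy, 0, 0)
  }

  # ---- distance cost ----
  e <- enclose_extent(b, bgt)
  gam <- 2 - ang
  d_dis <- c(0, 0, 0, 0)
  dis_gam_sens <- 0   # d distance / d gamma
  if (e$cw > 0) {
    rho <- (dx / e$cw)^2
    ex <- exp(-gam * rho)
    sel_r <- as.numeric(cx + w / 2 >= gx + gw / 2)
    sel_l <- as.numeric(cx - w / 2 <= gx - gw / 2)
    dcw <- c(sel_r - sel_l, 0, (sel_r + sel_l) / 2, 0)
    drho <- c(-2 * dx / e$cw^2, 0, 0, 0) - 2 * dx^2 / e$cw^3 * dcw
    d_dis <- d_dis + gam * ex * drho
    dis_gam_sens <- dis_gam_sens + rho * ex
  }
  if (e$ch > 0) {
    rho <- (dy / e$ch)^2
    ey <- exp(-gam * rho)
    sel_b <- as.numeric(cy + h / 2 >= gy + gh / 2)
    sel_t <- as.numeric(cy - h / 2 <= gy - gh / 2)
    dch <- c(0, sel_b - sel_t, 0, (sel_b + sel_t) / 2)
    drho <- c(0, -2 * dy / e$ch^2, 0, 0) - 2 * dy^2 / e$ch^3 * dch
    d_dis <- d_dis + gam * ey * drho
    dis_gam_sens <- dis_gam_sens + rho * ey
  }
  d_dis <- d_dis + dis_gam_sens * (-d_ang)   # gamma = 2 - angle

  # ---- shape cost ----
  th <- params$theta
  d_shp <- c(0, 0, 0, 0)
  mw <- max(w, gw)
  if (mw > 0) {
    om <- abs(w - gw) / mw
    dom_dw <- if (w > gw) gw / w^2 else if (w < gw) -1 / gw else 0
    d_shp[3] <- th * (1 - exp(-om))^(th - 1) * exp(-om) * dom_dw
  }
  mh <- max(h, gh)
  if (mh > 0) {
    om <- abs(h - gh) / mh
    dom_dh <- if (h > gh) gh / h^2 else if (h < gh) -1 / gh else 0
    d_shp[4] <- th * (1 - exp(-om))^(th - 1) * exp(-om) * dom_dh
  }

  g + (d_dis + d_shp) / 2
}

#' Comparator box-regression losses
#'
#' The standard published CIoU, DIoU, EIoU and GIoU losses (`1 - IoU` plus
#' the respective penalty), for side-by-side comparison harnesses.
#'
#' @param b,bgt predicted and ground-truth boxes.
#' @param kind one of `"ciou"`, `"diou"`, `"eiou"`, `"giou"`.
#' @param eps numerical guard.
#' @return scalar loss (0 for identical boxes).
#' @export
iou_family <- function(b, bgt, kind = c("ciou", "diou", "eiou", "giou"),
                       eps = 1e-9) {
  kind <- match.arg(kind)
  iou <- inner_iou(b, bgt, 1.0)
  e <- enclose_extent(b, bgt)
  dx <- bgt[[1]] - b[[1]]; dy <- bgt[[2]] - b[[2]]
  switch(kind,
    giou = {
      carea <- e$cw * e$ch
      A <- inner_box(b, 1); G <- inner_box(bgt, 1)
      inter <- max(0, min(A$r, G$r) - max(A$l, G$l)) *
               max(0, min(A$b, G$b) - max(A$t, G$t))
      uni <- b[[3]] * b[[4]] + bgt[[3]] * bgt[[4]] - inter
      giou <- if (carea > 0) iou - (carea - uni) / carea else iou
      1 - giou
    },
    diou = {
      c2 <- e$cw^2 + e$ch^2
      pen <- if (c2 > 0) (dx^2 + dy^2) / c2 else 0
      1 - iou + pen
    },
    ciou = {
      c2 <- e$cw^2 + e$ch^2
      pen <- if (c2 > 0) (dx^2 + dy^2) / c2 else 0
      v <- (4 / pi^2) *
        (atan2(bgt[[3]], bgt[[4]]) - atan2(b[[3]], b[[4]]))^2
      alpha <- if (v > 0) v / ((1 - iou) + v + eps) else 0
      1 - iou + pen + alpha * v
    },
    eiou = {
      c2 <- e$cw^2 + e$ch^2
      pen <- if (c2 > 0) (dx^2 + dy^2) / c2 else 0
      pw <- if (e$cw > 0) (b[[3]] - bgt[[3]])^2 / e$cw^2 else 0
      ph <- if (e$ch > 0) (b[[4]] - bgt[[4]])^2 / e$ch^2 else 0
      1 - iou + pen + pw + ph
    })
}
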