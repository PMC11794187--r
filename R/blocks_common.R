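# Module framework and the shared primitives: activations, the
# conv/normalize/activate unit, and fast spatial pyramid pooling (SPPF).

new_module <- function(class, ...) structure(list(...), class = c(class, "module"))

#' Run a module forward
#'
#' Generic forward pass. Feature maps are numeric arrays laid out
#' `(H, W, N, C)`; use [fm_from_chw()] / [fm_to_chw()] to convert from the
#' conventional single-image channels-first layout.
#'
#' @param m a module built by one of the block constructors.
#' @param x input feature map (array or autodiff node).
#' @param ... passed to methods.
#' @export
forward <- function(m, x, ...) UseMethod("forward")

#' Convert between channels-first and internal feature-map layout
#'
#' @param a for `fm_from_chw`, an array `(C, H, W)`; for `fm_to_chw`, an
#'   internal `(H, W, N, C)` array with `N = 1`.
#' @return the converted array.
#' @export
fm_from_chw <- function(a) {
  stopifnot(length(dim(a)) == 3)
  d <- dim(a)
  out <- aperm(a, c(2, 3, 1))
  dim(out) <- c(d[2], d[3], 1L, d[1])
  out
}

#' @rdname fm_from_chw
#' @export
fm_to_chw <- function(a) {
  a <- ag_value(a)
  d <- dim(a)
  stopifnot(length(d) == 4, d[3] == 1)
  dim(a) <- d[c(1, 2, 4)]
  aperm(a, c(3, 1, 2))
}

# ---- parameter collection ------------------------------------------------

#' Collect trainable parameter tensors of a module tree
#' @param m a module.
#' @return flat named list of autodiff leaves.
#' @export
module_params <- function(m) {
  out <- list()
  walk <- function(obj, prefix) {
    if (ag_is_node(obj)) {
      if (isTRUE(obj$requires_grad)) out[[prefix]] <<- obj
      return(invisible(NULL))
    }
    if (is.list(obj)) {
      nms <- names(obj)
      for (i in seq_along(obj)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(obj[[i]], paste(prefix, nm, sep = "."))
      }
    }
    invisible(NULL)
  }
  walk(unclass(m), "m")
  out
}

#' Count trainable parameters of a module
#' @param m a module.
#' @return integer count.
#' @export
n_parameters <- function(m) {
  sum(vapply(module_params(m), function(p) length(p$value), 0))
}

# ---- weight init ---------------------------------------------------------

init_conv_w <- function(k, cin, cout) {
  fan_in <- k * k * cin
  ag_leaf(array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                dim = c(k, k, cin, cout)), requires_grad = TRUE)
}

new_bn <- function(cc) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(cc)
  st$running_var <- rep(1, cc)
  list(gamma = ag_leaf(rep(1, cc), requires_grad = TRUE),
       beta = ag_leaf(numeric(cc), requires_grad = TRUE),
       state = st)
}

# ---- scalar activations --------------------------------------------------

#' Hard sigmoid and hard swish activations
#'
#' `hard_sigmoid(x) = clamp((x + 3) / 6, 0, 1)`; `h_swish(x) = x *
#' hard_sigmoid(x)`. Piecewise-linear surrogates of the sigmoid/swish pair,
#' cheap enough for embedded inference; `h_swish` equals `x` above 3 and 0
#' below -3.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' hard_sigmoid(c(-3, 0, 3))
#' h_swish(1)
#' @export
hard_sigmoid <- function(x) {
  stopifnot(all(is.finite(x)))
  pmin(pmax((x + 3) / 6, 0), 1)
}

#' @rdname hard_sigmoid
#' @export
h_swish <- function(x) x * hard_sigmoid(x)

# ---- conv / bn / act unit ------------------------------------------------

#' Convolution + normalization + activation unit
#'
#' The standard detector convolution unit: a same-padded, bias-free `k x k`
#' convolution followed by per-channel batch normalization and an activation.
#' Output spatial size is `ceil(H / s) x ceil(W / s)`.
#'
#' @param c_in,c_out input / output channel counts.
#' @param k odd kernel size.
#' @param s stride, 1 or 2.
#' @param act one of `"silu"`, `"hswish"`, `"relu"`, `"identity"`.
#' @param bn include batch normalization (if `FALSE` the conv carries a bias).
#' @return a module; run with [forward()].
#' @export
conv_bn_act <- function(c_in, c_out, k = 1L, s = 1L, act = "silu", bn = TRUE) {
  if (k %% 2 == 0) stop("kernel size must be odd")
  if (!s %in% c(1L, 2L)) stop("stride must be 1 or 2")
  new_module("conv_bn_act",
    w = init_conv_w(k, c_in, c_out),
    b = if (bn) NULL else ag_leaf(numeric(c_out), requires_grad = TRUE),
    bn = if (bn) new_bn(c_out) else NULL,
    k = k, s = s, act = act, c_in = c_in, c_out = c_out)
}

#' @export
forward.conv_bn_act <- function(m, x, ...) {
  y <- op_conv2d(x, m$w, m$b, stride = m$s)
  if (!is.null(m$bn)) y <- op_bn(y, m$bn$gamma, m$bn$beta, m$bn$state)
  op_act(y, m$act)
}

# Plain 1x1/3x3 conv with bias and no normalization (prediction layers).
conv_plain <- function(c_in, c_out, k = 1L) {
  new_module("conv_plain",
    w = init_conv_w(k, c_in, c_out),
    b = ag_leaf(numeric(c_out), requires_grad = TRUE),
    k = k, c_in = c_in, c_out = c_out)
}

#' @export
forward.conv_plain <- function(m, x, ...) op_conv2d(x, m$w, m$b, stride = 1L)

# ---- SPPF ----------------------------------------------------------------

#' Fast spatial pyramid pooling block
#'
#' Halves channels with a pointwise conv, applies three chained stride-1 max
#' pools of kernel `pool_k`, concatenates the four maps and fuses back to
#' `c_out` channels. Spatial size is unchanged.
#'
#' @param c_in,c_out channel counts (`c_out` defaults to `c_in`).
#' @param pool_k odd pooling kernel, default 5.
#' @param act activation for the two conv units.
#' @return a module.
#' @export
sppf <- function(c_in, c_out = c_in, pool_k = 5L, act = "silu") {
  if (pool_k %% 2 == 0) stop("pool kernel must be odd")
  ch <- c_in %/% 2L
  new_module("sppf",
    cv1 = conv_bn_act(c_in, ch, 1L, 1L, act),
    cv2 = conv_bn_act(ch * 4L, c_out, 1L, 1L, act),
    pool_k = pool_k)
}

#' @export
forward.sppf <- function(m, x, ...) {
  y0 <- forward(m$cv1, x)
  y1 <- op_maxpool_same(y0, m$pool_k)
  y2 <- op_maxpool_same(y1, m$pool_k)
  y3 <- op_maxpool_same(y2, m$pool_k)
  forward(m$cv2, op_concat_c(list(y0, y1, y2, y3)))
}
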