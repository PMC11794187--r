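# Partial convolution (PConv), the Faster block, its AMA-augmented variant,
# the C2f-Faster-AMA cross-stage block, and the baseline C2f it replaces.

#' Partial-convolution specification
#'
#' @param C total channel count of the map the conv acts on.
#' @param partial_ratio fraction of channels the dense conv touches
#'   (default 1/4); `c_p = max(1, round(C * partial_ratio))`.
#' @param k odd kernel size (default 3).
#' @param c_p explicit touched-channel count (overrides `partial_ratio`).
#' @return a list of class `pconv_spec`.
#' @export
pconv_spec <- function(C, partial_ratio = 0.25, k = 3L, c_p = NULL) {
  if (is.null(c_p)) c_p <- max(1L, as.integer(round(C * partial_ratio)))
  if (c_p > C) stop("c_p must not exceed C")
  if (k %% 2 == 0) stop("kernel size must be odd")
  structure(list(C = as.integer(C), c_p = as.integer(c_p), k = as.integer(k),
                 partial_ratio = c_p / C), class = "pconv_spec")
}

#' Partial convolution block
#'
#' A `k x k` bias-free convolution maps the first `c_p` channels to `c_p`
#' channels; the remaining `C - c_p` channels pass through untouched
#' (bit-identical). Shape-preserving; cuts compute and memory access roughly
#' by the partial ratio.
#'
#' @param spec a [pconv_spec()].
#' @return a module.
#' @export
pconv <- function(spec) {
  new_module("pconv",
    w = init_conv_w(spec$k, spec$c_p, spec$c_p),
    spec = spec)
}

#' @export
forward.pconv <- function(m, x, ...) {
  cp <- m$spec$c_p; C <- m$spec$C
  head_part <- op_slice_c(x, 1L, cp)
  y <- op_conv2d(head_part, m$w, NULL, stride = 1L)
  if (cp == C) return(y)
  op_concat_c(list(y, op_slice_c(x, cp + 1L, C)))
}

#' Memory-access cost of a partial convolution
#'
#' Exact access count `h*w*2*c_p + k^2*c_p^2` and its large-map
#' approximation `h*w*2*c_p`, both returned for reporting.
#'
#' @param h,w spatial extent of the feature map.
#' @param spec a [pconv_spec()].
#' @return list with elements `exact` and `approx`.
#' @examples
#' pconv_access_cost(64, 64, pconv_spec(64, c_p = 16))
#' @export
pconv_access_cost <- function(h, w, spec) {
  stopifnot(h >= 1, w >= 1)
  approx <- h * w * 2 * spec$c_p
  list(exact = approx + spec$k^2 * spec$c_p^2, approx = approx)
}

#' Faster block and its AMA-augmented variant
#'
#' `faster_block`: PConv -> 1x1 conv expanding to `2C` (+ BN + activation) ->
#' 1x1 bias-free conv back to `C` -> residual add. `faster_ama_block`
#' additionally applies the AMA gate to the branch output before the
#' residual add. Both preserve shape.
#'
#' @param C channel count.
#' @param partial_ratio fraction of channels the PConv touches.
#' @param act inner activation (default `"relu"`, the partial-conv network
#'   convention).
#' @param ama include the AMA gate on the branch.
#' @return a module.
#' @export
faster_block <- function(C, partial_ratio = 0.25, act = "relu", ama = FALSE) {
  new_module("faster_block",
    pc = pconv(pconv_spec(C, partial_ratio)),
    cv1 = conv_bn_act(C, 2L * C, 1L, 1L, act),
    cv2 = conv_raw(2L * C, C, 1L),
    ama = if (ama) ama_block(C) else NULL,
    C = C)
}

#' @rdname faster_block
#' @export
faster_ama_block <- function(C, partial_ratio = 0.25, act = "relu") {
  faster_block(C, partial_ratio, act, ama = TRUE)
}

#' @export
forward.faster_block <- function(m, x, ...) {
  b <- forward(m$pc, x)
  b <- forward(m$cv1, b)
  b <- forward(m$cv2, b)
  if (!is.null(m$ama)) b <- forward(m$ama, b)
  op_add(x, b)
}

# ---- C2f skeleton --------------------------------------------------------

#' Baseline residual bottleneck (two 3x3 conv units)
#' @param C channel count.
#' @param shortcut add the residual connection.
#' @param act activation.
#' @return a module.
#' @export
bottleneck_block <- function(C, shortcut = TRUE, act = "silu") {
  new_module("bottleneck_block",
    cv1 = conv_bn_act(C, C, 3L, 1L, act),
    cv2 = conv_bn_act(C, C, 3L, 1L, act),
    shortcut = shortcut, C = C)
}

#' @export
forward.bottleneck_block <- function(m, x, ...) {
  y <- forward(m$cv2, forward(m$cv1, x))
  if (m$shortcut) op_add(x, y) else y
}

c2f_skeleton <- function(c_in, c_out, n, make_block, act = "silu", type = "c2f") {
  if (c_out %% 2 != 0) stop("c_out must be even")
  hidden <- c_out %/% 2L
  new_module(type,
    cv1 = conv_bn_act(c_in, c_out, 1L, 1L, act),
    blocks = lapply(seq_len(n), function(i) make_block(hidden)),
    cv2 = conv_bn_act((2L + n) * hidden, c_out, 1L, 1L, act),
    hidden = hidden, n = n, c_in = c_in, c_out = c_out)
}

forward_c2f <- function(m, x) {
  y <- forward(m$cv1, x)
  a <- op_slice_c(y, 1L, m$hidden)
  b <- op_slice_c(y, m$hidden + 1L, 2L * m$hidden)
  parts <- list(a, b)
  cur <- b
  for (blk in m$blocks) {
    cur <- forward(blk, cur)
    parts[[length(parts) + 1L]] <- cur
  }
  forward(m$cv2, op_concat_c(parts))
}

#' Cross-stage blocks: baseline C2f and C2f-Faster-AMA
#'
#' Both share the C2f skeleton: a pointwise conv to `c_out` channels, a split
#' into two halves, `n` chained inner blocks each appending its output, a
#' concat of all `2 + n` branches and a pointwise fusion conv. `c2f` chains
#' baseline bottlenecks; `c2f_faster_ama` chains [faster_ama_block()]s,
#' which is what makes the block lighter at equal width and depth.
#'
#' @param c_in,c_out channel counts (`c_out` even).
#' @param n inner block count.
#' @param shortcut residual connection inside baseline bottlenecks.
#' @param act activation of the skeleton convs.
#' @param partial_ratio PConv ratio for the faster variant.
#' @return a module.
#' @export
c2f <- function(c_in, c_out, n = 1L, shortcut = TRUE, act = "silu") {
  c2f_skeleton(c_in, c_out, n,
               function(h) bottleneck_block(h, shortcut, act), act, "c2f")
}

#' @rdname c2f
#' @export
c2f_faster_ama <- function(c_in, c_out, n = 1L, partial_ratio = 0.25, act = "silu") {
  if (n < 1) stop("n must be >= 1")
  c2f_skeleton(c_in, c_out, n,
               function(h) faster_ama_block(h, partial_ratio), act, "c2f_faster_ama")
}

#' @export
forward.c2f <- function(m, x, ...) forward_c2f(m, x)

#' @export
forward.c2f_faster_ama <- function(m, x, ...) forward_c2f(m, x)
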