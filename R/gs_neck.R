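# Slim-neck blocks: GSConv (half dense conv + half depthwise conv with
# channel shuffle), the GSBottleneck residual unit, and the VOVGSCSPC
# cross-stage fusion block used at every neck fusion point.

#' Slim-neck block specification
#'
#' @param c_out output channels (even).
#' @param dw_k odd depthwise kernel size (default 5).
#' @param n bottleneck count (the fusion block uses 1).
#' @return a list of class `gs_spec`.
#' @export
gs_spec <- function(c_out, dw_k = 5L, n = 1L) {
  stopifnot(c_out %% 2 == 0, dw_k %% 2 == 1, n >= 1)
  structure(list(c_out = as.integer(c_out), dw_k = as.integer(dw_k),
                 n = as.integer(n)), class = "gs_spec")
}

dwconv_bn_act <- function(C, k = 5L, act = "silu") {
  new_module("dwconv_bn_act",
    w = ag_leaf(array(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))), dim = c(k, k, C)),
                requires_grad = TRUE),
    bn = new_bn(C), act = act, C = C, k = k)
}

#' @export
forward.dwconv_bn_act <- function(m, x, ...) {
  y <- op_dwconv2d(x, m$w)
  y <- op_bn(y, m$bn$gamma, m$bn$beta, m$bn$state)
  op_act(y, m$act)
}

op_permute_c <- function(x, perm) {
  xv <- ag_value(x)
  y <- xv[, , , perm, drop = FALSE]
  inv <- order(perm)
  ag_node(y, list(x), function(g) list(g[, , , inv, drop = FALSE]))
}

#' GSConv: half dense, half depthwise convolution with channel shuffle
#'
#' A standard conv unit maps to `c_out / 2` channels (kernel `k`, stride
#' `s`), a depthwise conv unit (kernel `dw_k`) processes that half again, the
#' two halves are concatenated and interleaved by a fixed channel shuffle.
#' The shuffle is a permutation, so the multiset of values at each spatial
#' location is preserved.
#'
#' @param c_in,c_out channel counts (`c_out` even).
#' @param k dense-conv kernel size.
#' @param s stride.
#' @param dw_k depthwise kernel size.
#' @param act activation (`"identity"` disables, as in pre-residual units).
#' @return a module.
#' @export
gsconv <- function(c_in, c_out, k = 1L, s = 1L, dw_k = 5L, act = "silu") {
  if (c_out %% 2 != 0) stop("c_out must be even")
  h <- c_out %/% 2L
  # interleave dense half a and depthwise half b as a1 b1 a2 b2 ...
  perm <- as.vector(rbind(seq_len(h), seq_len(h) + h))
  new_module("gsconv",
    cv = conv_bn_act(c_in, h, k, s, act),
    dw = dwconv_bn_act(h, dw_k, act),
    perm = perm, c_in = c_in, c_out = c_out)
}

#' @export
forward.gsconv <- function(m, x, ...) {
  a <- forward(m$cv, x)
  b <- forward(m$dw, a)
  op_permute_c(op_concat_c(list(a, b)), m$perm)
}

#' GSBottleneck residual unit
#'
#' Main path: pointwise conv to `C/2`, then two chained GSConvs (dense
#' kernels 1 and 3) holding `C/2` channels. Shortcut: a pointwise,
#' activation-free conv of the input to `C/2`. Output is the elementwise
#' sum, `C/2` channels.
#'
#' @param C input channels (even).
#' @param dw_k depthwise kernel of the GSConvs.
#' @param act activation.
#' @return a module.
#' @export
gs_bottleneck <- function(C, dw_k = 5L, act = "silu") {
  if (C %% 2 != 0) stop("C must be even")
  h <- C %/% 2L
  new_module("gs_bottleneck",
    proj = conv_bn_act(C, h, 1L, 1L, act),
    gs1 = gsconv(h, h, 1L, 1L, dw_k, act),
    gs2 = gsconv(h, h, 3L, 1L, dw_k, act),
    shortcut = conv_bn_act(C, h, 1L, 1L, "identity"),
    C = C, c_out = h)
}

#' @export
forward.gs_bottleneck <- function(m, x, ...) {
  y <- forward(m$gs2, forward(m$gs1, forward(m$proj, x)))
  op_add(y, forward(m$shortcut, x))
}

#' VOVGSCSPC cross-stage fusion block
#'
#' A pointwise conv brings the input to the working width `c_out`; a
#' [gs_bottleneck()] reduces it to `c_out / 2`; a parallel pointwise conv of
#' the raw input provides the other `c_out / 2`; the concatenation (exactly
#' `c_out` channels) is fused by a final pointwise conv. The working width is
#' tied to the output width so the block compresses wide fusion inputs,
#' which is where its parameter savings over the baseline C2f come from.
#'
#' @param c_in,c_out channel counts (`c_out` even).
#' @param spec a [gs_spec()]; defaults to `gs_spec(c_out)`.
#' @param act activation.
#' @return a module.
#' @export
vovgscspc <- function(c_in, c_out, spec = gs_spec(c_out), act = "silu") {
  h <- c_out %/% 2L
  new_module("vovgscspc",
    cv1 = conv_bn_act(c_in, c_out, 1L, 1L, act),
    gsb = gs_bottleneck(c_out, spec$dw_k, act),
    cv2 = conv_bn_act(c_in, h, 1L, 1L, act),
    cv3 = conv_bn_act(c_out, c_out, 1L, 1L, act),
    c_in = c_in, c_out = c_out)
}

#' @export
forward.vovgscspc <- function(m, x, ...) {
  a <- forward(m$gsb, forward(m$cv1, x))
  b <- forward(m$cv2, x)
  forward(m$cv3, op_concat_c(list(a, b)))
}
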