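# Average-and-Max pooling channel attention (AMA): global average and max
# pooled channel descriptors, a shared cross-channel 1-D convolution whose
# kernel size adapts to the channel count, sigmoid gating, channel reweight.

#' Configuration of the AMA attention block
#'
#' The cross-channel 1-D convolution kernel size adapts to the channel count
#' `C` through `K = round_odd((a * C^0.35 + b) / g)`.
#'
#' @param a,b,g coefficients of the adaptive-kernel map (defaults 2, 1, 4).
#' @param exponent channel exponent, fixed at 0.35.
#' @param min_kernel odd lower bound for the kernel size.
#' @return a list of class `ama_config`.
#' @export
ama_config <- function(a = 2, b = 1, g = 4, exponent = 0.35, min_kernel = 1L) {
  stopifnot(a > 0, g > 0, min_kernel >= 1, min_kernel %% 2 == 1)
  structure(list(a = a, b = b, g = g, exponent = exponent,
                 min_kernel = as.integer(min_kernel)),
            class = "ama_config")
}

#' Adaptive kernel size from channel count
#'
#' Evaluates `(a * C^0.35 + b) / g`, rounds to the nearest odd integer (ties
#' toward the larger odd value) and floors at `min_kernel`.
#'
#' @param C channel count, `C >= 1`.
#' @param cfg an [ama_config()].
#' @return odd integer kernel size.
#' @examples
#' kernel_from_channels(64)   # 3
#' kernel_from_channels(512)  # 5
#' @export
kernel_from_channels <- function(C, cfg = ama_config()) {
  if (any(C < 1)) stop("C must be >= 1")
  t <- (cfg$a * C^cfg$exponent + cfg$b) / cfg$g
  k <- 2L * as.integer(floor((t - 1) / 2 + 0.5)) + 1L
  pmax(k, cfg$min_kernel)
}

#' Channel count from kernel size (inverse map)
#'
#' Exact functional inverse of the un-rounded adaptive-kernel map:
#' `C = ((g * K - b) / a)^(1 / 0.35)`.
#'
#' @param K kernel size, `K >= 1`; `g * K - b` must be positive.
#' @inheritParams kernel_from_channels
#' @return real channel count.
#' @export
channels_from_kernel <- function(K, cfg = ama_config()) {
  if (any(K < 1)) stop("K must be >= 1")
  u <- (cfg$g * K - cfg$b) / cfg$a
  if (any(u <= 0)) stop("g * K - b must be positive")
  u^(1 / cfg$exponent)
}

#' AMA channel attention block
#'
#' Global average and max pooling give two C-vectors; both pass through one
#' shared bias-free cross-channel 1-D convolution (kernel size from
#' [kernel_from_channels()]); the responses are summed, squashed by a sigmoid
#' into per-channel weights in (0,1), and the input channels are rescaled.
#' Shape-preserving and attenuation-only.
#'
#' @param C channel count the block attends over.
#' @param cfg an [ama_config()].
#' @return a module.
#' @export
ama_block <- function(C, cfg = ama_config()) {
  K <- kernel_from_channels(C, cfg)
  new_module("ama_block",
    w = ag_leaf(stats::rnorm(K, sd = 0.5), requires_grad = TRUE),
    C = C, K = K, gate_on = TRUE)
}

#' @export
forward.ama_block <- function(m, x, ...) {
  if (!isTRUE(m$gate_on)) return(x)
  ga <- op_gap(x)
  gm <- op_gmp(x)
  r <- op_add(op_conv1d_channels(ga, m$w), op_conv1d_channels(gm, m$w))
  op_mul_channel(x, op_sigmoid(r))
}

#' Channel weights computed by an AMA block
#'
#' Returns the sigmoid gate values (one per channel and batch element)
#' without applying them, for inspection and testing.
#'
#' @param m an [ama_block()].
#' @param x feature map `(H, W, N, C)`.
#' @return matrix `(N, C)` of weights in (0,1).
#' @export
ama_weights <- function(m, x) {
  ag_no_grad({
    ga <- op_gap(x)
    gm <- op_gmp(x)
    ag_value(op_sigmoid(op_add(op_conv1d_channels(ga, m$w),
                               op_conv1d_channels(gm, m$w))))
  })
}
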