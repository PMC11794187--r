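# DenseAMA: a densely connected backbone stage (DenseNet-style pre-activation
# layers with AMA attention and hard-swish), closed by a transition that
# compresses channels and halves the spatial size.

#' Configuration of the DenseAMA stage
#'
#' @param in_channels channels entering the stage (the stem output width).
#' @param growth_rate channels appended by every dense layer.
#' @param num_layers number of dense layers before the transition.
#' @param bottleneck_factor width multiplier of the 1x1 expansion
#'   (bottleneck width = `bottleneck_factor * growth_rate`).
#' @param out_channels channels after the transition.
#' @return a list of class `dense_config`.
#' @export
dense_config <- function(in_channels = 32L,
                         # (growth 16, 3 layers, bottleneck x3): sized so the
                         # assembled single-class detector lands on its 8.8 M
                         # parameter / 28.2 GFLOP budget; see the vignette.
                         growth_rate = 16L, num_layers = 3L,
                         bottleneck_factor = 3L, out_channels = 64L) {
  stopifnot(growth_rate >= 1, num_layers >= 1, out_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 growth_rate = as.integer(growth_rate),
                 num_layers = as.integer(num_layers),
                 bottleneck_factor = as.integer(bottleneck_factor),
                 out_channels = as.integer(out_channels)),
            class = "dense_config")
}

conv_raw <- function(c_in, c_out, k = 1L) {
  new_module("conv_raw", w = init_conv_w(k, c_in, c_out), c_in = c_in, c_out = c_out)
}

#' @export
forward.conv_raw <- function(m, x, ...) op_conv2d(x, m$w, NULL, stride = 1L)

#' Dense layer with AMA attention
#'
#' Pre-activation bottleneck layer: BN -> hard-swish -> 1x1 conv
#' (`bottleneck_factor * growth_rate` channels) -> BN -> hard-swish -> 3x3
#' conv (`growth_rate` channels) -> AMA gate; the branch output is
#' concatenated onto the input, so the first `c_in` output channels are
#' bit-identical to the input (dense connectivity).
#'
#' @param c_in input channels for this layer.
#' @param cfg a [dense_config()].
#' @return a module producing `c_in + growth_rate` channels.
#' @export
dense_layer_ama <- function(c_in, cfg = dense_config()) {
  bw <- cfg$bottleneck_factor * cfg$growth_rate
  new_module("dense_layer_ama",
    bn1 = new_bn(c_in),
    conv1 = conv_raw(c_in, bw, 1L),
    bn2 = new_bn(bw),
    conv2 = conv_raw(bw, cfg$growth_rate, 3L),
    ama = ama_block(cfg$growth_rate),
    c_in = c_in, c_out = c_in + cfg$growth_rate)
}

#' @export
forward.dense_layer_ama <- function(m, x, ...) {
  b <- op_bn(x, m$bn1$gamma, m$bn1$beta, m$bn1$state)
  b <- op_act(b, "hswish")
  b <- forward(m$conv1, b)
  b <- op_bn(b, m$bn2$gamma, m$bn2$beta, m$bn2$state)
  b <- op_act(b, "hswish")
  b <- forward(m$conv2, b)
  b <- forward(m$ama, b)
  op_concat_c(list(x, b))
}

#' Transition layer with AMA attention
#'
#' BN -> hard-swish -> AMA gate -> 1x1 compression conv to `out_channels` ->
#' 2x2 average pooling (stride 2). Requires even spatial extent; output is
#' `(out_channels, H/2, W/2)`. The compression conv is what lets the dense
#' stage match the downstream backbone width.
#'
#' @param c_in input channels.
#' @param cfg a [dense_config()].
#' @return a module.
#' @export
transit_ama <- function(c_in, cfg = dense_config()) {
  new_module("transit_ama",
    bn = new_bn(c_in),
    ama = ama_block(c_in),
    conv = conv_raw(c_in, cfg$out_channels, 1L),
    c_in = c_in, c_out = cfg$out_channels)
}

#' @export
forward.transit_ama <- function(m, x, ...) {
  d <- dim(ag_value(x))
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) stop("transit_ama requires even H and W")
  y <- op_bn(x, m$bn$gamma, m$bn$beta, m$bn$state)
  y <- op_act(y, "hswish")
  y <- forward(m$ama, y)
  y <- forward(m$conv, y)
  op_avgpool2(y)
}

#' DenseAMA backbone stage
#'
#' `num_layers` dense layers followed by one transition; consumes the stem
#' output and produces the stride-doubled stage-1 feature map of the
#' backbone.
#'
#' @param cfg a [dense_config()].
#' @return a module.
#' @export
dense_ama_stage <- function(cfg = dense_config()) {
  layers <- list()
  cc <- cfg$in_channels
  for (i in seq_len(cfg$num_layers)) {
    layers[[i]] <- dense_layer_ama(cc, cfg)
    cc <- cc + cfg$growth_rate
  }
  new_module("dense_ama_stage",
    layers = layers,
    transit = transit_ama(cc, cfg),
    cfg = cfg, c_in = cfg$in_channels, c_out = cfg$out_channels)
}

#' @export
forward.dense_ama_stage <- function(m, x, ...) {
  for (ly in m$layers) x <- forward(ly, x)
  forward(m$transit, x)
}
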