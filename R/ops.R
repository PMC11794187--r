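# Differentiable array ops. Feature maps are numeric arrays laid out
# (H, W, N, C): channels last so channel concat/split are contiguous and the
# im2col views flatten straight into (H*W*N) x C matrices for BLAS.

pad_hw <- function(x, p, fill = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  xp
}

conv_out_len <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

# 2-D convolution, weight (k, k, Cin, Cout), optional bias (Cout). Computed
# as a sum over the k^2 kernel offsets of one GEMM each, which keeps peak
# memory at one shifted view instead of a full im2col matrix.
op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- if (is.null(b)) NULL else ag_value(b)
  d <- dim(xv); k <- dim(wv)[1]; cin <- dim(wv)[3]; cout <- dim(wv)[4]
  stopifnot(d[4] == cin)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  ho <- conv_out_len(d[1], k, stride, pad)
  wo <- conv_out_len(d[2], k, stride, pad)
  n <- d[3]
  xp <- pad_hw(xv, pad)
  rows <- ho * wo * n
  ym <- matrix(0, rows, cout)
  ri <- lapply(seq_len(k), function(kh) seq(kh, by = stride, length.out = ho))
  ci <- lapply(seq_len(k), function(kw) seq(kw, by = stride, length.out = wo))
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    xs <- xp[ri[[kh]], ci[[kw]], , , drop = FALSE]
    dim(xs) <- c(rows, cin)
    ym <- ym + xs %*% wv[kh, kw, , ]
  }
  if (!is.null(bv)) ym <- ym + rep(bv, each = rows)
  ag_add_flops(rows * cin * cout * k * k)
  y <- ym
  dim(y) <- c(ho, wo, n, cout)
  ag_node(y, list(x, w, b), function(g) {
    gm <- g; dim(gm) <- c(rows, cout)
    need_dx <- ag_is_node(x)
    dxp <- if (need_dx) array(0, dim = dim(xp)) else NULL
    dw <- array(0, dim = dim(wv))
    for (kh in seq_len(k)) for (kw in seq_len(k)) {
      xs <- xp[ri[[kh]], ci[[kw]], , , drop = FALSE]
      dim(xs) <- c(rows, cin)
      dw[kh, kw, , ] <- crossprod(xs, gm)
      if (need_dx) {
        dxs <- gm %*% t(wv[kh, kw, , ])
        dim(dxs) <- c(ho, wo, n, cin)
        dxp[ri[[kh]], ci[[kw]], , ] <- dxp[ri[[kh]], ci[[kw]], , , drop = FALSE] + dxs
      }
    }
    dx <- NULL
    if (need_dx) {
      dx <- dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , , drop = FALSE]
      dim(dx) <- d
    }
    db <- if (is.null(b)) NULL else colSums(gm)
    list(dx, dw, db)
  })
}

# Depthwise convolution, weight (k, k, C), stride 1, same padding.
op_dwconv2d <- function(x, w) {
  xv <- ag_value(x); wv <- ag_value(w)
  d <- dim(xv); k <- dim(wv)[1]; cc <- d[4]
  pad <- (k - 1L) %/% 2L
  xp <- pad_hw(xv, pad)
  y <- array(0, dim = d)
  hwn <- d[1] * d[2] * d[3]
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    xs <- xp[kh:(kh + d[1] - 1L), kw:(kw + d[2] - 1L), , , drop = FALSE]
    y <- y + xs * rep(wv[kh, kw, ], each = hwn)
  }
  ag_add_flops(hwn * cc * k * k)
  ag_node(y, list(x, w), function(g) {
    need_dx <- ag_is_node(x)
    dxp <- if (need_dx) array(0, dim = dim(xp)) else NULL
    dw <- array(0, dim = dim(wv))
    gm <- g; dim(gm) <- c(hwn, cc)
    for (kh in seq_len(k)) for (kw in seq_len(k)) {
      xs <- xp[kh:(kh + d[1] - 1L), kw:(kw + d[2] - 1L), , , drop = FALSE]
      xsm <- xs; dim(xsm) <- c(hwn, cc)
      dw[kh, kw, ] <- colSums(xsm * gm)
      if (need_dx) {
        dxp[kh:(kh + d[1] - 1L), kw:(kw + d[2] - 1L), , ] <-
          dxp[kh:(kh + d[1] - 1L), kw:(kw + d[2] - 1L), , , drop = FALSE] +
          g * rep(wv[kh, kw, ], each = hwn)
      }
    }
    dx <- NULL
    if (need_dx) dx <- dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , , drop = FALSE]
    list(dx, dw)
  })
}

# Cross-channel 1-D convolution on pooled descriptors m (N, C), shared kernel
# w (length K, odd), zero padding, single in/out channel, bias-free.
op_conv1d_channels <- function(m, w) {
  mv <- ag_value(m); wv <- ag_value(w)
  n <- nrow(mv); cc <- ncol(mv); kk <- length(wv)
  p <- (kk - 1L) %/% 2L
  mp <- cbind(matrix(0, n, p), mv, matrix(0, n, p))
  y <- matrix(0, n, cc)
  for (j in seq_len(kk)) y <- y + wv[j] * mp[, j:(j + cc - 1L), drop = FALSE]
  ag_add_flops(n * cc * kk)
  ag_node(y, list(m, w), function(g) {
    dw <- vapply(seq_len(kk), function(j) sum(g * mp[, j:(j + cc - 1L)]), 0)
    dmp <- matrix(0, n, cc + 2L * p)
    for (j in seq_len(kk)) {
      dmp[, j:(j + cc - 1L)] <- dmp[, j:(j + cc - 1L)] + wv[j] * g
    }
    list(dmp[, (p + 1L):(p + cc), drop = FALSE], dw)
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# carrying running_mean / running_var, updated only in training mode.
op_bn <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim(xv); m <- d[1] * d[2] * d[3]; cc <- d[4]
  xm <- xv; dim(xm) <- c(m, cc)
  if (ag_is_training()) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- xm - rep(mu, each = m)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = m)
  ym <- xhat * rep(gv, each = m) + rep(bv, each = m)
  y <- ym; dim(y) <- d
  train_stats <- ag_is_training()
  ag_node(y, list(x, gamma, beta), function(g) {
    gm <- g; dim(gm) <- c(m, cc)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (train_stats) {
      # full batch-statistics backward
      dxhat <- gm * rep(gv, each = m)
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * xhat)
      dxm <- (dxhat - rep(t1, each = m) - xhat * rep(t2, each = m)) * rep(istd, each = m)
    } else {
      dxm <- gm * rep(gv * istd, each = m)
    }
    dx <- dxm; dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

op_act <- function(x, kind = c("silu", "hswish", "relu", "identity")) {
  kind <- match.arg(kind)
  if (kind == "identity") return(x)
  xv <- ag_value(x)
  y <- switch(kind,
    silu = { s <- 1 / (1 + exp(-xv)); xv * s },
    hswish = xv * pmin(pmax((xv + 3) / 6, 0), 1),
    relu = pmax(xv, 0)
  )
  ag_node(y, list(x), function(g) {
    dydx <- switch(kind,
      silu = { s <- 1 / (1 + exp(-xv)); s * (1 + xv * (1 - s)) },
      hswish = ifelse(xv >= 3, 1, ifelse(xv <= -3, 0, (2 * xv + 3) / 6)),
      relu = (xv > 0) + 0
    )
    list(g * dydx)
  })
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_value(x)))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# Max pooling, stride 1, same padding (as used by fast pyramid pooling).
op_maxpool_same <- function(x, k) {
  xv <- ag_value(x)
  d <- dim(xv); p <- (k - 1L) %/% 2L
  xp <- pad_hw(xv, p, fill = -Inf)
  dp <- dim(xp)
  n_el <- prod(d)
  best <- array(-Inf, dim = d)
  best_idx <- integer(n_el)
  # linear index of (h, w, n, c) in padded array for offset (kh, kw)
  base_h <- rep.int(seq_len(d[1]), times = d[2] * d[3] * d[4])
  base_w <- rep.int(rep(seq_len(d[2]), each = d[1]), times = d[3] * d[4])
  base_nc <- rep(seq_len(d[3] * d[4]) - 1L, each = d[1] * d[2])
  for (kh in seq_len(k)) for (kw in seq_len(k)) {
    idx <- (base_nc * dp[2] + (base_w + kw - 2L)) * dp[1] + base_h + kh - 1L
    v <- xp[idx]
    better <- v > best
    best[better] <- v[better]
    best_idx[better] <- idx[better]
  }
  ag_node(best, list(x), function(g) {
    acc <- rowsum(as.vector(g), group = best_idx)
    dxp <- array(0, dim = dp)
    dxp[as.integer(rownames(acc))] <- acc
    dx <- dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , , drop = FALSE]
    list(dx)
  })
}

# 2x2 average pooling, stride 2 (H, W even).
op_avgpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  oh <- seq(1L, d[1], by = 2L); ohe <- oh + 1L
  ow <- seq(1L, d[2], by = 2L); owe <- ow + 1L
  y <- (xv[oh, ow, , , drop = FALSE] + xv[ohe, ow, , , drop = FALSE] +
        xv[oh, owe, , , drop = FALSE] + xv[ohe, owe, , , drop = FALSE]) / 4
  ag_node(y, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[oh, ow, , ] <- g / 4
    dx[ohe, ow, , ] <- g / 4
    dx[oh, owe, , ] <- g / 4
    dx[ohe, owe, , ] <- g / 4
    list(dx)
  })
}

# Global average / max pooling over (H, W): (H,W,N,C) -> (N,C).
op_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  xm <- xv; dim(xm) <- c(hw, d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  ag_node(y, list(x), function(g) {
    dx <- rep(as.vector(g) / hw, each = hw)
    dim(dx) <- d
    list(dx)
  })
}

op_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  xm <- xv; dim(xm) <- c(hw, d[3] * d[4])
  win <- apply(xm, 2, which.max)
  y <- matrix(xm[cbind(win, seq_along(win))], d[3], d[4])
  ag_node(y, list(x), function(g) {
    dxm <- matrix(0, hw, d[3] * d[4])
    dxm[cbind(win, seq_along(win))] <- as.vector(g)
    dim(dxm) <- d
    list(dxm)
  })
}

# Nearest-neighbour x2 upsampling.
op_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    oh <- seq(1L, 2L * d[1], by = 2L); ow <- seq(1L, 2L * d[2], by = 2L)
    dx <- g[oh, ow, , , drop = FALSE] + g[oh + 1L, ow, , , drop = FALSE] +
      g[oh, ow + 1L, , , drop = FALSE] + g[oh + 1L, ow + 1L, , , drop = FALSE]
    list(dx)
  })
}

# Concatenate along the channel axis (last dim: plain vector concat).
op_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  dims <- lapply(vals, dim)
  cs <- vapply(dims, function(d) d[4], 0L)
  d0 <- dims[[1]]
  y <- array(unlist(vals, use.names = FALSE), dim = c(d0[1], d0[2], d0[3], sum(cs)))
  ends <- cumsum(cs)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(y, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , , starts[i]:ends[i], drop = FALSE])
  })
}

op_slice_c <- function(x, from, to) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[, , , from:to, drop = FALSE]
  ag_node(y, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , , from:to] <- g
    list(dx)
  })
}

op_add <- function(a, b) {
  y <- ag_value(a) + ag_value(b)
  ag_node(y, list(a, b), function(g) list(g, g))
}

# Per-channel gating: x (H,W,N,C) scaled by s (N,C).
op_mul_channel <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim(xv)
  hw <- d[1] * d[2]
  y <- xv * rep(as.vector(sv), each = hw)
  ag_node(y, list(x, s), function(g) {
    dx <- g * rep(as.vector(sv), each = hw)
    prod <- g * xv
    dim(prod) <- c(hw, d[3] * d[4])
    ds <- matrix(colSums(prod), d[3], d[4])
    list(dx, ds)
  })
}
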