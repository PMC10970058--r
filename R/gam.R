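# Global attention mechanism: sequential channel-then-spatial gating.
# The channel submodule permutes the map so channels are the trailing axis,
# runs every positional channel vector through a shared two-layer
# perceptron with a bottleneck, permutes back and squashes through a
# sigmoid; the gate multiplies the input elementwise. The spatial
# submodule models local context with two 7x7 convolutions (C -> C/r,
# BN + ReLU, C/r -> C) and gates the same way. Both preserve shape.

#' GAM configuration
#'
#' @param channels channel count `C` of the attended feature map
#' @param reduction_ratio bottleneck divisor `r`; the perceptron and the
#'   7x7 convolutions operate at width `C / r`. Must divide `channels`.
#'   The grading network fixes the bottleneck width at 8 channels
#'   (`r = C/8`) at both of its placements.
#' @return an object of class `gam_config`
#' @export
gam_config <- function(channels, reduction_ratio = channels / 8L) {
  channels <- as.integer(channels)
  reduction_ratio <- as.integer(reduction_ratio)
  if (channels <= 0L || reduction_ratio <= 0L) stop("channels and reduction_ratio must be positive")
  if (channels %% reduction_ratio != 0L) stop("reduction_ratio must divide channels")
  structure(list(channels = channels, reduction_ratio = reduction_ratio,
                 hidden = channels %/% reduction_ratio),
            class = "gam_config")
}

mod_gam_channel <- function(channels, hidden) {
  new_module("gam_channel", channels = channels, hidden = hidden,
    shapes = list(w1 = c(channels, hidden), b1 = hidden,
                  w2 = c(hidden, channels), b2 = channels),
    inits = list(w1 = "tn", b1 = "zeros", w2 = "tn", b2 = "zeros"))
}

nn_fw.mod_gam_channel <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[3L] != m$channels) stop(sprintf("expected %d channels, got %d", m$channels, d[3L]))
  mm <- to_cl(x)
  a <- sweep(mm %*% m$par$w1, 2L, m$par$b1, `+`, check.margin = FALSE)
  ar <- pmax(a, 0)
  s <- sweep(ar %*% m$par$w2, 2L, m$par$b2, `+`, check.margin = FALSE)
  gate <- sigmoid(s)
  if (training) m$cache <- list(d = d, mm = mm, a = a, ar = ar, gate = gate, x = x)
  x * from_cl(gate, d)
}

nn_bw.mod_gam_channel <- function(m, dy, need_dx = TRUE) {
  cc <- m$cache
  d <- cc$d
  gate4 <- from_cl(cc$gate, d)
  dgate <- to_cl(dy * cc$x)
  ds <- dgate * cc$gate * (1 - cc$gate)
  m$grad$w2 <- m$grad$w2 + crossprod(cc$ar, ds)
  m$grad$b2 <- m$grad$b2 + colSums(ds)
  dar <- tcrossprod(ds, m$par$w2)
  da <- dar * (cc$a > 0)
  m$grad$w1 <- m$grad$w1 + crossprod(cc$mm, da)
  m$grad$b1 <- m$grad$b1 + colSums(da)
  if (!need_dx) return(NULL)
  dy * gate4 + from_cl(tcrossprod(da, m$par$w1), d)
}

mod_gam_spatial <- function(channels, hidden) {
  new_module("gam_spatial", channels = channels, hidden = hidden,
    children = list(conv1 = mod_conv2d(channels, hidden, 7L, pad = 3L),
                    conv2 = mod_conv2d(hidden, channels, 7L, pad = 3L)),
    shapes = list(bn_w = hidden, bn_b = hidden),
    inits = list(bn_w = "ones", bn_b = "zeros"),
    buf = list(run_mean = numeric(hidden), run_var = rep(1, hidden)))
}

nn_fw.mod_gam_spatial <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[3L] != m$channels) stop(sprintf("expected %d channels, got %d", m$channels, d[3L]))
  u <- nn_fw(m$children$conv1, x, training)
  du <- dim(u)
  bn <- bn_fw(to_cl(u), m$par$bn_w, m$par$bn_b, m$buf$run_mean, m$buf$run_var, training)
  if (training) {
    m$buf$run_mean <- bn$run_mean
    m$buf$run_var <- bn$run_var
  }
  v <- pmax(bn$y, 0)
  s <- nn_fw(m$children$conv2, from_cl(v, du), training)
  gate <- sigmoid(s)
  if (training) m$cache <- list(d = d, du = du, bn = bn, bn_y = bn$y, gate = gate, x = x)
  x * gate
}

nn_bw.mod_gam_spatial <- function(m, dy, need_dx = TRUE) {
  cc <- m$cache
  dgate <- dy * cc$x * cc$gate * (1 - cc$gate)
  dv4 <- nn_bw(m$children$conv2, dgate, need_dx = TRUE)
  dv <- to_cl(dv4) * (cc$bn_y > 0)
  bb <- bn_bw(dv, cc$bn, m$par$bn_w, training = TRUE)
  m$grad$bn_w <- m$grad$bn_w + bb$dw
  m$grad$bn_b <- m$grad$bn_b + bb$db
  dx1 <- nn_bw(m$children$conv1, from_cl(bb$dx, cc$du), need_dx = need_dx)
  if (!need_dx) return(NULL)
  dy * cc$gate + dx1
}

mod_gam <- function(cfg) {
  new_module("gam", cfg = cfg,
    children = list(ch = mod_gam_channel(cfg$channels, cfg$hidden),
                    sp = mod_gam_spatial(cfg$channels, cfg$hidden)))
}

nn_fw.mod_gam <- function(m, x, training = FALSE) {
  nn_fw(m$children$sp, nn_fw(m$children$ch, x, training), training)
}

nn_bw.mod_gam <- function(m, dy, need_dx = TRUE) {
  nn_bw(m$children$ch, nn_bw(m$children$sp, dy, need_dx = TRUE), need_dx = need_dx)
}

#' Build a global attention module
#'
#' @param config a [gam_config()]
#' @return a shape-preserving attention module; apply with [gam_apply()]
#'   or [nn_forward()]
#' @export
build_gam <- function(config) {
  stopifnot(inherits(config, "gam_config"))
  mod_gam(config)
}

#' Apply channel attention
#'
#' Elementwise product of the input with a sigmoid channel gate computed by
#' the module's shared two-layer perceptron. Output shape equals input
#' shape; with all-zero weights the gate is exactly 0.5 everywhere.
#'
#' @param gam a module from [build_gam()]
#' @param x activation array `(H, W, C)` or `(H, W, C, N)`
#' @return gated array of the same shape
#' @export
channel_attention <- function(gam, x) {
  stopifnot(inherits(gam, "mod_gam"))
  nn_forward(gam$children$ch, x)
}

#' Apply spatial attention
#'
#' Elementwise product of the input with a sigmoid spatial gate computed by
#' two 7x7 convolutions through the bottleneck width.
#'
#' @inheritParams channel_attention
#' @return gated array of the same shape
#' @export
spatial_attention <- function(gam, x) {
  stopifnot(inherits(gam, "mod_gam"))
  nn_forward(gam$children$sp, x)
}

#' Apply the full attention module (channel then spatial)
#'
#' @inheritParams channel_attention
#' @return gated array of the same shape; with all-zero weights the output
#'   is exactly `0.25 * x` (two successive 0.5 gates)
#' @export
gam_apply <- function(gam, x) {
  stopifnot(inherits(gam, "mod_gam"))
  nn_forward(gam, x)
}
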