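# Layer and composite modules. Forward methods cache (in training mode or
# whenever `m$keep_cache` is set by the surrounding network) exactly what
# their backward methods need.

# ---- grouped 2-d convolution -----------------------------------------

mod_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                       bias = TRUE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  shapes <- list(w = c(k, k, cin %/% groups, cout))
  inits <- list(w = "tn")
  if (bias) {
    shapes$b <- cout
    inits$b <- "zeros"
  }
  new_module("conv2d", cin = cin, cout = cout, k = k, stride = as.integer(stride),
             pad = as.integer(pad), groups = as.integer(groups),
             shapes = shapes, inits = inits)
}

nn_fw.mod_conv2d <- function(m, x, training = FALSE) {
  if (dim(x)[3L] != m$cin) {
    stop(sprintf("expected %d input channels, got %d", m$cin, dim(x)[3L]))
  }
  if (training) m$cache <- list(x = x)
  conv2d_fw_cpp(x, m$par$w, m$par$b, m$stride, m$pad, m$groups)
}

nn_bw.mod_conv2d <- function(m, dy, need_dx = TRUE) {
  g <- conv2d_bw_cpp(m$cache$x, m$par$w, dy, m$stride, m$pad, m$groups, need_dx)
  m$grad$w <- m$grad$w + g$dw
  if (!is.null(m$par$b)) m$grad$b <- m$grad$b + g$db
  if (need_dx) g$dx else NULL
}

# ---- sequential container --------------------------------------------

mod_seq <- function(children) {
  if (is.null(names(children))) {
    names(children) <- sprintf("l%d", seq_along(children))
  }
  new_module("seq", children = children)
}

nn_fw.mod_seq <- function(m, x, training = FALSE) {
  for (ch in m$children) x <- nn_fw(ch, x, training)
  x
}

nn_bw.mod_seq <- function(m, dy, need_dx = TRUE) {
  n <- length(m$children)
  for (i in rev(seq_len(n))) {
    dy <- nn_bw(m$children[[i]], dy, need_dx = need_dx || i > 1L)
  }
  dy
}

# ---- ConvNeXt block ---------------------------------------------------
# 7x7 depthwise conv -> channel LN -> 1x1 expand x4 -> GELU -> 1x1 project
# -> learnable per-channel scale -> stochastic-depth residual add.

mod_block <- function(dim, drop_path = 0, layer_scale_init = 1e-6) {
  hid <- 4L * dim
  new_module("block",
    dim = dim, drop_path = drop_path, layer_scale_init = layer_scale_init,
    children = list(dw = mod_conv2d(dim, dim, 7L, pad = 3L, groups = dim)),
    shapes = list(ln_w = dim, ln_b = dim, w1 = c(dim, hid), b1 = hid,
                  w2 = c(hid, dim), b2 = dim, gamma = dim),
    inits = list(ln_w = "ones", ln_b = "zeros", w1 = "tn", b1 = "zeros",
                 w2 = "tn", b2 = "zeros", gamma = "lscale"))
}

nn_fw.mod_block <- function(m, x, training = FALSE) {
  d <- dim(x)
  r <- nn_fw(m$children$dw, x, training)
  mm <- to_cl(r)
  ln <- ln_fw(mm, m$par$ln_w, m$par$ln_b)
  h1 <- ln$y %*% m$par$w1
  h1 <- sweep(h1, 2L, m$par$b1, `+`, check.margin = FALSE)
  g <- gelu(h1)
  h2 <- g %*% m$par$w2
  h2 <- sweep(h2, 2L, m$par$b2, `+`, check.margin = FALSE)
  s <- sweep(h2, 2L, m$par$gamma, `*`, check.margin = FALSE)
  res <- from_cl(s, d)
  keep <- NULL
  if (training && m$drop_path > 0) {
    keep <- stats::rbinom(d[4L], 1L, 1 - m$drop_path) / (1 - m$drop_path)
    res <- res * rep(keep, each = prod(d[1:3]))
  }
  if (training) {
    m$cache <- list(d = d, ln = ln, ln_in = mm, h1 = h1, g = g, h2 = h2, keep = keep)
  }
  x + res
}

nn_bw.mod_block <- function(m, dy, need_dx = TRUE) {
  cc <- m$cache
  d <- cc$d
  dres <- dy
  if (!is.null(cc$keep)) dres <- dres * rep(cc$keep, each = prod(d[1:3]))
  ds <- to_cl(dres)
  m$grad$gamma <- m$grad$gamma + colSums(ds * cc$h2)
  dh2 <- sweep(ds, 2L, m$par$gamma, `*`, check.margin = FALSE)
  m$grad$w2 <- m$grad$w2 + crossprod(cc$g, dh2)
  m$grad$b2 <- m$grad$b2 + colSums(dh2)
  dg <- tcrossprod(dh2, m$par$w2)
  dh1 <- dg * gelu_grad(cc$h1)
  m$grad$w1 <- m$grad$w1 + crossprod(cc$ln$y, dh1)
  m$grad$b1 <- m$grad$b1 + colSums(dh1)
  dln_y <- tcrossprod(dh1, m$par$w1)
  lb <- ln_bw(dln_y, cc$ln, m$par$ln_w)
  m$grad$ln_w <- m$grad$ln_w + lb$dw
  m$grad$ln_b <- m$grad$ln_b + lb$db
  dr <- from_cl(lb$dx, d)
  dx_dw <- nn_bw(m$children$dw, dr, need_dx = need_dx)
  if (need_dx) dy + dx_dw else NULL
}

# ---- stem: 4x4 stride-4 conv + channel LN ----------------------------

mod_stem <- function(cin, cout) {
  new_module("stem",
    children = list(conv = mod_conv2d(cin, cout, 4L, stride = 4L)),
    shapes = list(ln_w = cout, ln_b = cout),
    inits = list(ln_w = "ones", ln_b = "zeros"))
}

nn_fw.mod_stem <- function(m, x, training = FALSE) {
  y <- nn_fw(m$children$conv, x, training)
  d <- dim(y)
  ln <- ln_fw(to_cl(y), m$par$ln_w, m$par$ln_b)
  if (training) m$cache <- list(d = d, ln = ln)
  from_cl(ln$y, d)
}

nn_bw.mod_stem <- function(m, dy, need_dx = TRUE) {
  cc <- m$cache
  lb <- ln_bw(to_cl(dy), cc$ln, m$par$ln_w)
  m$grad$ln_w <- m$grad$ln_w + lb$dw
  m$grad$ln_b <- m$grad$ln_b + lb$db
  nn_bw(m$children$conv, from_cl(lb$dx, cc$d), need_dx = need_dx)
}

# ---- inter-stage downsampler: channel LN + 2x2 stride-2 conv ---------

mod_downsample <- function(cin, cout) {
  new_module("downsample",
    children = list(conv = mod_conv2d(cin, cout, 2L, stride = 2L)),
    shapes = list(ln_w = cin, ln_b = cin),
    inits = list(ln_w = "ones", ln_b = "zeros"))
}

nn_fw.mod_downsample <- function(m, x, training = FALSE) {
  d <- dim(x)
  ln <- ln_fw(to_cl(x), m$par$ln_w, m$par$ln_b)
  if (training) m$cache <- list(d = d, ln = ln)
  nn_fw(m$children$conv, from_cl(ln$y, d), training)
}

nn_bw.mod_downsample <- function(m, dy, need_dx = TRUE) {
  dln <- nn_bw(m$children$conv, dy, need_dx = TRUE)
  cc <- m$cache
  lb <- ln_bw(to_cl(dln), cc$ln, m$par$ln_w)
  m$grad$ln_w <- m$grad$ln_w + lb$dw
  m$grad$ln_b <- m$grad$ln_b + lb$db
  if (need_dx) from_cl(lb$dx, cc$d) else NULL
}

# ---- classification head: global average pool -> LN -> linear --------

mod_head <- function(cin, num_classes) {
  new_module("head", cin = cin, num_classes = as.integer(num_classes),
    shapes = list(ln_w = cin, ln_b = cin, w = c(cin, num_classes), b = num_classes),
    inits = list(ln_w = "ones", ln_b = "zeros", w = "tn", b = "zeros"))
}

nn_fw.mod_head <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L] * d[2L], d[3L] * d[4L])
  pooled <- matrix(colMeans(xm), d[3L], d[4L])  # C x N
  z <- t(pooled)                                # N x C
  ln <- ln_fw(z, m$par$ln_w, m$par$ln_b)
  logits <- sweep(ln$y %*% m$par$w, 2L, m$par$b, `+`, check.margin = FALSE)
  if (training) m$cache <- list(d = d, ln = ln)
  logits
}

nn_bw.mod_head <- function(m, dy, need_dx = TRUE) {
  cc <- m$cache
  d <- cc$d
  m$grad$w <- m$grad$w + crossprod(cc$ln$y, dy)
  m$grad$b <- m$grad$b + colSums(dy)
  dz <- tcrossprod(dy, m$par$w)
  lb <- ln_bw(dz, cc$ln, m$par$ln_w)
  m$grad$ln_w <- m$grad$ln_w + lb$dw
  m$grad$ln_b <- m$grad$ln_b + lb$db
  if (!need_dx) return(NULL)
  dpool <- t(lb$dx) / (d[1L] * d[2L])           # C x N, spread over positions
  dx <- array(rep(dpool, each = d[1L] * d[2L]), dim = d)
  dx
}

# ---- channel reduction + 2x spatial upsampling -----------------------

mod_reduce_upsample <- function(cin, target_channels,
                                mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (target_channels <= 0) stop("target_channels must be positive")
  new_module("reduce_upsample", mode = mode, target = as.integer(target_channels),
             children = list(conv = mod_conv2d(cin, target_channels, 1L)))
}

interp_mats <- function(m, h, w) {
  key <- sprintf("%d_%d", h, w)
  if (is.null(m$mats)) m$mats <- list()
  if (is.null(m$mats[[key]])) {
    m$mats[[key]] <- list(ah = upsample2x_matrix(h, m$mode),
                          aw = upsample2x_matrix(w, m$mode))
  }
  m$mats[[key]]
}

nn_fw.mod_reduce_upsample <- function(m, x, training = FALSE) {
  r <- nn_fw(m$children$conv, x, training)
  d <- dim(r)
  mats <- interp_mats(m, d[1L], d[2L])
  interp_hw(r, mats$ah, mats$aw)
}

nn_bw.mod_reduce_upsample <- function(m, dy, need_dx = TRUE) {
  d2 <- dim(dy)
  mats <- interp_mats(m, d2[1L] %/% 2L, d2[2L] %/% 2L)
  dr <- interp_hw(dy, t(mats$ah), t(mats$aw))
  nn_bw(m$children$conv, dr, need_dx = need_dx)
}

# ---- fusion: ordered channel concatenation + ConvNeXt blocks ---------

mod_fuse <- function(c_a, c_b, n_blocks = 3L, drop_path = 0,
                     layer_scale_init = 1e-6) {
  blocks <- lapply(seq_len(n_blocks), function(i) {
    mod_block(c_a + c_b, drop_path = drop_path, layer_scale_init = layer_scale_init)
  })
  names(blocks) <- sprintf("b%d", seq_len(n_blocks))
  new_module("fuse", c_a = as.integer(c_a), c_b = as.integer(c_b),
             children = list(blocks = mod_seq(blocks)))
}

nn_fw.mod_fuse <- function(m, x, training = FALSE) {
  a <- x[[1L]]
  b <- x[[2L]]
  da <- dim(a)
  db <- dim(b)
  if (any(da[c(1L, 2L, 4L)] != db[c(1L, 2L, 4L)])) {
    stop("fusion inputs must share spatial and batch extents")
  }
  if (da[3L] != m$c_a || db[3L] != m$c_b) stop("fusion channel plan mismatch")
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  if (training) m$cache <- list(c_a = da[3L])
  nn_fw(m$children$blocks, y, training)
}

nn_bw.mod_fuse <- function(m, dy, need_dx = TRUE) {
  dcat <- nn_bw(m$children$blocks, dy, need_dx = need_dx)
  if (!need_dx) return(NULL)
  ca <- m$cache$c_a
  list(dcat[, , seq_len(ca), , drop = FALSE],
       dcat[, , (ca + 1L):dim(dcat)[3L], , drop = FALSE])
}

# list inputs bypass the array normalisation in nn_forward()
nn_forward_pair <- function(m, a, b, training = FALSE) {
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  if (length(dim(b)) == 3L) dim(b) <- c(dim(b), 1L)
  nn_fw(m, list(a, b), training)
}
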