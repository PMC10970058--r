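# Low-level array/matrix primitives shared by the network layers.
# Activation layout everywhere: a 4-d array (H, W, C, N).

# (H,W,C,N) <-> channels-last matrix (H*W*N, C)
to_cl <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

from_cl <- function(m, d) {
  dim(m) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(m, c(1L, 2L, 4L, 3L))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Layer normalisation over the channel axis of a positions x channels matrix.
ln_fw <- function(m, w, b, eps = 1e-6) {
  mu <- rowMeans(m)
  xc <- m - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = sweep(xhat * w[col(xhat)], 2L, b, `+`, check.margin = FALSE),
       xhat = xhat, istd = istd)
}

ln_bw <- function(dy, cache, w) {
  xhat <- cache$xhat
  dxhat <- dy * w[col(dy)]
  dx <- cache$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dw = colSums(dy * xhat), db = colSums(dy))
}

# Batch normalisation over the row (position/batch) axis, per channel column.
bn_fw <- function(m, w, b, run_mean, run_var, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu, check.margin = FALSE)
    v <- colMeans(xc * xc)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(m, 2L, mu, check.margin = FALSE)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`, check.margin = FALSE)
  y <- sweep(sweep(xhat, 2L, w, `*`, check.margin = FALSE), 2L, b, `+`, check.margin = FALSE)
  list(y = y, xhat = xhat, istd = istd, run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(dy, cache, w, training) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, w, `*`, check.margin = FALSE)
  if (training) {
    mh <- colMeans(dxhat)
    mxh <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2L, mh, check.margin = FALSE) -
                  sweep(xhat, 2L, mxh, `*`, check.margin = FALSE),
                2L, cache$istd, `*`, check.margin = FALSE)
  } else {
    dx <- sweep(dxhat, 2L, cache$istd, `*`, check.margin = FALSE)
  }
  list(dx = dx, dw = colSums(dy * xhat), db = colSums(dy))
}

# Interpolation matrix mapping n input rows to 2n output rows.
upsample2x_matrix <- function(n, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  a <- matrix(0, 2L * n, n)
  if (mode == "nearest") {
    a[cbind(seq_len(2L * n), rep(seq_len(n), each = 2L))] <- 1
  } else {
    src <- (seq_len(2L * n) - 0.5) / 2 - 0.5
    i0 <- pmin(pmax(floor(src), 0), n - 1)
    i1 <- pmin(i0 + 1, n - 1)
    fr <- src - floor(src)
    fr[src < 0] <- 0
    for (i in seq_len(2L * n)) {
      a[i, i0[i] + 1L] <- a[i, i0[i] + 1L] + (1 - fr[i])
      a[i, i1[i] + 1L] <- a[i, i1[i] + 1L] + fr[i]
    }
  }
  a
}

# Apply row-interpolation matrices along H and W of an (H,W,C,N) array.
interp_hw <- function(x, ah, aw) {
  d <- dim(x)
  m <- matrix(x, d[1L], prod(d[-1L]))
  t1 <- ah %*% m
  h2 <- nrow(ah)
  dim(t1) <- c(h2, d[2L], d[3L], d[4L])
  t1 <- aperm(t1, c(2L, 1L, 3L, 4L))
  m2 <- matrix(t1, d[2L], h2 * d[3L] * d[4L])
  t2 <- aw %*% m2
  w2 <- nrow(aw)
  dim(t2) <- c(w2, h2, d[3L], d[4L])
  aperm(t2, c(2L, 1L, 3L, 4L))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Truncated-normal initialiser
#'
#' Samples from N(0, sd^2) truncated at two standard deviations, the
#' convention used for convolution and linear weights throughout the package.
#'
#' @param n number of draws
#' @param sd standard deviation before truncation
#' @return numeric vector of length `n`
#' @keywords internal
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}
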