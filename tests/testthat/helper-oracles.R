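# Shared fixtures and independent scalar-loop oracles. The oracles
# deliberately avoid the package's vectorised code paths.

rand_img <- function(h = 32L, w = h, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(h * w * 3L * n), c(h, w, 3L, n))
}

rand_img_c <- function(h, w, chan, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(h * w * chan * n), c(h, w, chan, n))
}

rand_probs <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# a deliberately small grading network used where only wiring matters
small_pegg_cfg <- function() {
  backbone_config(depths = c(1, 1, 1, 1), dims = c(4, 8, 16, 32), num_classes = 5)
}

small_pegg <- function(seed = 1L, with_gam = TRUE) {
  m <- build_pegg(small_pegg_cfg(), gam_config(8, 2), gam_config(16, 2),
                  msff_config(fusion_block_count = 1, fuse1_channels = 32,
                              fuse2_channels = 16),
                  with_gam = with_gam)
  init_parameters(m, seed)
  m
}

# explicit per-sample loops over Eq.-style definitions
ce_scalar <- function(pred, labels) {
  s <- 0
  for (i in seq_len(nrow(pred))) s <- s - log(max(pred[i, labels[i]], 1e-12))
  s / nrow(pred)
}

fl_scalar <- function(pred, labels, alpha, gamma) {
  s <- 0
  for (i in seq_len(nrow(pred))) {
    pt <- max(pred[i, labels[i]], 1e-12)
    s <- s + (-alpha[labels[i]] * (1 - pt)^gamma * log(pt))
  }
  s / nrow(pred)
}

# one-vs-rest metrics from explicit TP/FP/FN/TN counting
metrics_scalar <- function(cm, i) {
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f)
}

rand_cm5 <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rpois(25, lambda = stats::runif(1, 1, 20)), 5, 5,
              dimnames = list(true = egg_labels(), predicted = egg_labels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}
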