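# helpers to probe the rendered scenes
egg_region <- function(img) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  lum > 0.12
}

# angular spread of the yolk (dark disk inside the translucent egg) radius:
# dark pixels within a radial cutoff of the yolk's position (slightly below
# the centroid of the bright albumen), binned by angle; the cutoff keeps
# the dark background and egg rim out of the measurement
yolk_radius_spread <- function(img) {
  s <- nrow(img)
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  bright <- which(lum > 0.2, arr.ind = TRUE)
  if (nrow(bright) < 20) return(NA_real_)
  yc <- mean(bright[, 1]) + 0.08 * s
  xc <- mean(bright[, 2])
  dark <- which(lum < 0.12, arr.ind = TRUE)
  r0 <- sqrt((dark[, 1] - yc)^2 + (dark[, 2] - xc)^2)
  dark <- dark[r0 < 0.24 * s, , drop = FALSE]
  if (nrow(dark) < 20) return(NA_real_)
  cy <- mean(dark[, 1])
  cx <- mean(dark[, 2])
  th <- atan2(dark[, 1] - cy, dark[, 2] - cx)
  r <- sqrt((dark[, 1] - cy)^2 + (dark[, 2] - cx)^2)
  bins <- cut(th, breaks = seq(-pi, pi, length.out = 17))
  rmax <- tapply(r, bins, max)
  stats::sd(rmax, na.rm = TRUE) / mean(rmax, na.rm = TRUE)
}

test_that("generation is deterministic under seed and validates inputs", {
  p <- synthetic_egg_params(size = 32, seed = 6)
  d1 <- generate_synthetic_dataset(p, c(QP = 2, IP = 1))
  d2 <- generate_synthetic_dataset(p, c(QP = 2, IP = 1))
  expect_identical(d1, d2)
  d3 <- generate_synthetic_dataset(synthetic_egg_params(size = 32, seed = 7),
                                   c(QP = 2, IP = 1))
  expect_false(identical(d1$images, d3$images))
  expect_error(synthetic_egg_params(size = 0), "positive")
  expect_error(generate_synthetic_dataset(p, c(XX = 2)), "unknown labels")
  expect_error(generate_synthetic_dataset(p, c(QP = -1)), "nonnegative")
  expect_identical(as.character(d1$labels), c("QP", "QP", "IP"))
})

test_that("class-conditional luminance ordering holds on generated batches", {
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 64, seed = 8),
                                   c(QP = 5, PP = 5, IP = 5))
  lum <- function(im) mean((im[, , 1] + im[, , 2] + im[, , 3]) / 3)
  egg_lum <- vapply(ds$images, function(im) {
    l <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    mean(l[egg_region(im)])
  }, numeric(1))
  # inferior eggs are nearly opaque: their whole-egg luminance sits below the
  # albumen luminance of pale eggs, and far below qualified eggs
  ip_all <- vapply(ds$images[11:15], lum, numeric(1))
  pp_albumen <- egg_lum[6:10]
  qp_albumen <- egg_lum[1:5]
  expect_true(max(ip_all) < min(pp_albumen))
  expect_true(min(qp_albumen) > max(ip_all))
  expect_gt(mean(qp_albumen), mean(pp_albumen))
})

test_that("broken-yolk eggs have a rougher yolk boundary than qualified eggs", {
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 96, seed = 9),
                                   c(QP = 6, BYP = 6))
  spread <- vapply(ds$images, yolk_radius_spread, numeric(1))
  expect_gt(mean(spread[7:12], na.rm = TRUE), mean(spread[1:6], na.rm = TRUE))
})

test_that("a trivial pixel-statistics classifier beats chance on generated data", {
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 48, seed = 10),
                                   c(QP = 8, PP = 8, BYP = 8, YYP = 8, IP = 8))
  feats <- t(vapply(ds$images, function(im) {
    c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3]),
      yolk_radius_spread(im))
  }, numeric(4)))
  feats[is.na(feats)] <- 0
  lab <- as.integer(ds$labels)
  train <- unlist(lapply(split(seq_along(lab), lab), head, 4))
  test <- setdiff(seq_along(lab), train)
  centroids <- apply(feats[train, ], 2, function(col) tapply(col, lab[train], mean))
  scale <- apply(feats[train, ], 2, stats::sd)
  scale[scale == 0] <- 1
  pred <- apply(feats[test, ], 1, function(f) {
    which.min(colSums(((t(centroids) - f) / scale)^2))
  })
  acc <- mean(pred == lab[test])
  expect_gt(acc, 0.2)  # chance level for five balanced classes
})
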