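test_that("cross-entropy matches hand-evaluated cases", {
  # certain prediction on the true class
  p <- matrix(c(1, 0, 0, 0, 0), 1)
  expect_equal(cross_entropy(p, 1), 0, tolerance = 1e-10)
  # uniform prediction over five classes
  u <- matrix(rep(0.2, 5), 1)
  expect_equal(cross_entropy(u, 3), -log(0.2), tolerance = 1e-12)
  # batch mean of two per-sample losses
  two <- rbind(c(0.5, 0.5, 0, 0, 0), rep(0.2, 5))
  expect_equal(cross_entropy(two, c(1, 2)), (-log(0.5) - log(0.2)) / 2,
               tolerance = 1e-12)
})

test_that("focal loss matches hand-evaluated cases and its limits", {
  prm <- loss_params(alpha = rep(0.25, 5), gamma = 2)
  p <- matrix(c(0.5, 0.5, 0, 0, 0), 1)
  expect_equal(focal_loss(p, 1, prm), 0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(round(focal_loss(p, 1, prm), 6), 0.043322)
  # perfect prediction vanishes for any alpha/gamma
  sure <- matrix(c(0, 1, 0, 0, 0), 1)
  expect_equal(focal_loss(sure, 2, loss_params(alpha = rep(7, 5), gamma = 3)), 0,
               tolerance = 1e-9)
  # gamma = 0, alpha = 1 recovers cross-entropy
  ident <- loss_params(alpha = rep(1, 5), gamma = 0)
  q <- rand_probs(8, 5, seed = 1)
  lab <- sample.int(5, 8, replace = TRUE)
  expect_equal(focal_loss(q, lab, ident), cross_entropy(q, lab), tolerance = 1e-12)
  expect_equal(combined_loss(q, lab, ident), cross_entropy(q, lab), tolerance = 1e-12)
})

test_that("the 0.5/0.5 blend matches hand arithmetic and stays nonnegative", {
  prm <- loss_params(alpha = rep(0.25, 5), gamma = 2)
  p <- matrix(c(0.5, 0.5, 0, 0, 0), 1)
  expect_equal(combined_loss(p, 1, prm), 0.5 * log(2) + 0.5 * 0.0625 * log(2),
               tolerance = 1e-12)
  expect_equal(combined_loss(p, 1, prm), 0.368235, tolerance = 1e-5)
  for (s in 1:5) {
    q <- rand_probs(6, 5, seed = s)
    lab <- sample.int(5, 6, replace = TRUE)
    expect_gte(combined_loss(q, lab, prm), 0)
  }
})

test_that("invalid probability inputs are rejected", {
  expect_error(cross_entropy(matrix(c(0.5, 0.6, 0, 0, 0), 1), 1), "sum to 1")
  expect_error(cross_entropy(matrix(c(1.5, -0.5, 0, 0, 0), 1), 1), "\\[0, 1\\]")
  expect_error(cross_entropy(matrix(rep(0.2, 5), 1), 7), "labels")
  expect_error(cross_entropy(rand_probs(3, 5), c(1, 2)), "match")
  expect_error(loss_params(gamma = -1), "gamma")
  expect_error(loss_params(alpha = c(-1, 1, 1, 1, 1)), "alpha")
})

test_that("focal loss decreases in p_t and is bounded by alpha * CE", {
  prm <- loss_params(alpha = rep(0.7, 5), gamma = 2)
  pts <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(pts, function(pt) {
    focal_loss(matrix(c(pt, 1 - pt, 0, 0, 0), 1), 1, prm)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  for (pt in pts) {
    p <- matrix(c(pt, 1 - pt, 0, 0, 0), 1)
    expect_lte(focal_loss(p, 1, prm), 0.7 * cross_entropy(p, 1) + 1e-12)
  }
})

test_that("vectorised losses agree with scalar-loop oracles", {
  for (s in 1:5) {
    q <- rand_probs(16, 5, seed = s)
    set.seed(100 + s)
    lab <- sample.int(5, 16, replace = TRUE)
    alpha <- stats::runif(5, 0.2, 2)
    gam <- stats::runif(1, 0, 4)
    prm <- loss_params(alpha = alpha, gamma = gam)
    expect_equal(cross_entropy(q, lab), ce_scalar(q, lab), tolerance = 1e-10)
    expect_equal(focal_loss(q, lab, prm), fl_scalar(q, lab, alpha, gam),
                 tolerance = 1e-10)
    expect_equal(combined_loss(q, lab, prm),
                 0.5 * ce_scalar(q, lab) + 0.5 * fl_scalar(q, lab, alpha, gam),
                 tolerance = 1e-10)
  }
})

test_that("logit-level gradients agree with finite differences", {
  set.seed(11)
  z <- matrix(stats::rnorm(4 * 5), 4, 5)
  lab <- c(1L, 3L, 5L, 2L)
  prm <- loss_params(alpha = stats::runif(5, 0.5, 1.5), gamma = 2)
  lg <- peggnet:::softmax_loss_grad(z, lab, prm)
  expect_equal(lg$loss, 0.5 * lg$ce + 0.5 * lg$fl, tolerance = 1e-12)
  eps <- 1e-6
  for (i in 1:4) {
    for (j in 1:5) {
      zp <- z; zp[i, j] <- zp[i, j] + eps
      zm <- z; zm[i, j] <- zm[i, j] - eps
      fd <- (peggnet:::softmax_loss_grad(zp, lab, prm)$loss -
               peggnet:::softmax_loss_grad(zm, lab, prm)$loss) / (2 * eps)
      expect_equal(lg$grad[i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("inverse-frequency weights are proportional to 1/n_c with mean 1", {
  labels <- rep(1:5, c(50, 10, 20, 10, 10))
  a <- peggnet:::resolve_alpha(loss_params(alpha = "inverse_frequency"), labels, 5)
  expect_equal(mean(a), 1)
  expect_equal(a[1] / a[2], 10 / 50)
})
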