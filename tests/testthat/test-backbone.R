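test_that("named presets carry the published per-stage depths and widths", {
  t2 <- list(
    tiny   = list(c(3, 3, 9, 3),  c(96, 192, 384, 768)),
    small  = list(c(3, 3, 27, 3), c(96, 192, 384, 768)),
    base   = list(c(3, 3, 27, 3), c(128, 256, 512, 1024)),
    large  = list(c(3, 3, 27, 3), c(192, 384, 768, 1536)),
    xlarge = list(c(3, 3, 27, 3), c(256, 512, 1024, 2048)),
    nano   = list(c(3, 3, 9, 3),  c(64, 128, 256, 512))
  )
  for (nm in names(t2)) {
    cfg <- backbone_config(nm)
    expect_equal(cfg$depths, t2[[nm]][[1]], ignore_attr = TRUE)
    expect_equal(cfg$dims, t2[[nm]][[2]], ignore_attr = TRUE)
  }
})

test_that("invalid backbone configurations are rejected", {
  expect_error(backbone_config(depths = c(3, 3, 9), dims = c(96, 192, 384, 768)),
               "length 4")
  expect_error(backbone_config(depths = c(3, 3, 9, 3), dims = c(96, 192, -384, 768)),
               "positive")
  expect_error(backbone_config("nano", num_classes = 0), "num_classes")
  expect_error(backbone_config("nano", drop_path_rate = 1), "drop_path_rate")
})

test_that("single-layer parameter counts follow the kernel arithmetic", {
  # 7x7 depthwise over 64 channels with bias: 64*49 + 64
  expect_equal(count_parameters(peggnet:::mod_conv2d(64, 64, 7, groups = 64)), 3200)
  # lone linear map 768 -> 5 with bias (as a 1x1 convolution): 768*5 + 5
  expect_equal(count_parameters(peggnet:::mod_conv2d(768, 5, 1)), 3845)
  # a ConvNeXt block at width C has 8C^2 + 58C parameters
  expect_equal(count_parameters(peggnet:::mod_block(96)), 8 * 96^2 + 58 * 96)
})

test_that("stage outputs obey stride arithmetic over random input sizes", {
  cfg <- backbone_config(depths = c(1, 1, 1, 1), dims = c(4, 8, 16, 32))
  m <- build_backbone(cfg)
  init_parameters(m, 1)
  set.seed(42)
  for (s in sample(c(32L, 64L, 96L, 160L), 3)) {
    fs <- forward_features(m, rand_img(s, s))
    for (i in 1:4) {
      side <- as.integer(s %/% (4 * 2^(i - 1)))
      expect_identical(dim(fs[[i]]), c(side, side, cfg$dims[i], 1L))
    }
  }
})

test_that("nano stage shapes at 64px and batches are preserved", {
  m <- build_backbone(backbone_config("nano"))
  init_parameters(m, 2)
  fs <- forward_features(m, rand_img(64, 64, n = 2, seed = 1))
  expect_identical(vapply(fs, function(f) dim(f)[3L], integer(1)),
                   c(64L, 128L, 256L, 512L))
  expect_identical(vapply(fs, function(f) dim(f)[1L], integer(1)),
                   c(16L, 8L, 4L, 2L))
  expect_true(all(vapply(fs, function(f) dim(f)[4L], integer(1)) == 2L))
})

test_that("bad image inputs are rejected", {
  m <- build_backbone(backbone_config(depths = c(1, 1, 1, 1), dims = c(4, 8, 16, 32)))
  init_parameters(m, 1)
  expect_error(forward_features(m, array(0, c(64, 64, 5, 1))), "channels")
  expect_error(forward_features(m, array(0, c(50, 50, 3, 1))), "divisible by 32")
  expect_error(nn_forward(m, rand_img(32)),
               NA)
})

test_that("evaluation-mode forward passes are bitwise reproducible", {
  m <- build_backbone(backbone_config(depths = c(1, 1, 1, 1), dims = c(4, 8, 16, 32)))
  init_parameters(m, 3)
  x <- rand_img(64, seed = 9)
  expect_identical(nn_forward(m, x), nn_forward(m, x))
})

test_that("zero stochastic depth makes training and evaluation passes agree", {
  cfg <- backbone_config(depths = c(2, 1, 1, 1), dims = c(4, 8, 16, 32),
                         drop_path_rate = 0)
  m <- build_backbone(cfg)
  init_parameters(m, 4)
  x <- rand_img(32, seed = 11)
  expect_equal(nn_forward(m, x, training = TRUE), nn_forward(m, x, training = FALSE))
})

test_that("nonzero stochastic depth perturbs training passes but not eval", {
  cfg <- backbone_config(depths = c(2, 1, 1, 1), dims = c(4, 8, 16, 32),
                         drop_path_rate = 0.9)
  m <- build_backbone(cfg)
  init_parameters(m, 4)
  x <- rand_img(32, n = 4, seed = 12)
  set.seed(1)
  tr <- replicate(4, sum(nn_forward(m, x, training = TRUE)))
  expect_gt(stats::sd(tr), 0)
  expect_identical(nn_forward(m, x), nn_forward(m, x))
})

test_that("initialisation is deterministic under a fixed seed", {
  cfg <- backbone_config(depths = c(1, 1, 1, 1), dims = c(4, 8, 16, 32))
  m1 <- init_parameters(build_backbone(cfg), 7)
  m2 <- init_parameters(build_backbone(cfg), 7)
  expect_identical(get_state(m1), get_state(m2))
  m3 <- init_parameters(build_backbone(cfg), 8)
  expect_false(identical(get_state(m1), get_state(m3)))
})
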