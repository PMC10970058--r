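table1_totals <- c(QP = 692, PP = 332, BYP = 523, YYP = 323, IP = 257)

test_that("the per-class floor rule reproduces the published split grid", {
  labels <- rep(names(table1_totals), table1_totals)
  subsets <- split_dataset(labels, split_spec(seed = 1))
  grid <- split_table(labels, subsets)
  expect_identical(unname(grid["train", egg_labels()]),
                   c(484L, 232L, 366L, 226L, 179L))
  expect_identical(unname(grid["validation", egg_labels()]),
                   c(138L, 66L, 104L, 64L, 51L))
  expect_identical(unname(grid["test", egg_labels()]),
                   c(70L, 34L, 53L, 33L, 27L))
  expect_identical(unname(grid[, "Total"]), c(1487L, 423L, 217L, 2127L))
})

test_that("splits partition every class for random sizes", {
  set.seed(20)
  for (rep in 1:5) {
    sizes <- sample(3:40, 5)
    labels <- rep(egg_labels(), sizes)
    subsets <- split_dataset(labels, split_spec(seed = rep))
    expect_false(anyNA(subsets))
    f <- factor(labels, levels = egg_labels())
    for (i in 1:5) {
      n <- sizes[i]
      cnt <- table(subsets[f == egg_labels()[i]])
      expect_identical(unname(cnt["train"]), as.integer(floor(0.7 * n)))
      expect_identical(unname(cnt["validation"]), as.integer(floor(0.2 * n)))
      expect_identical(sum(cnt), n)
    }
  }
})

test_that("split specs and inputs are validated", {
  expect_error(split_spec(c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(split_dataset(rep("QP", 10)), "empty classes")
  expect_error(split_dataset(rep("foo", 3)), "unknown labels")
})

test_that("seeded splits are reproducible and seed-sensitive", {
  labels <- rep(egg_labels(), c(20, 20, 20, 20, 20))
  s1 <- split_dataset(labels, split_spec(seed = 5))
  s2 <- split_dataset(labels, split_spec(seed = 5))
  s3 <- split_dataset(labels, split_spec(seed = 6))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("augmentation multiplies counts exactly and preserves labels", {
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 24, seed = 2),
                                   c(QP = 2, PP = 1, IP = 2))
  for (f in c(1L, 3L, 10L)) {
    aug <- augment_training_set(ds, augment_spec(factor = f, seed = 1))
    expect_length(aug$images, f * length(ds$images))
    expect_identical(as.character(aug$labels),
                     as.character(ds$labels[aug$source]))
    expect_true(all(vapply(aug$images, function(im) identical(dim(im), c(24L, 24L, 3L)),
                           logical(1))))
    # first copy of each source is the identity
    firsts <- !duplicated(aug$source)
    expect_identical(aug$images[firsts], ds$images)
  }
})

test_that("augmentation is byte-identical under a fixed seed", {
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 24, seed = 3),
                                   c(QP = 2, BYP = 1))
  a1 <- augment_training_set(ds, augment_spec(seed = 9))
  a2 <- augment_training_set(ds, augment_spec(seed = 9))
  a3 <- augment_training_set(ds, augment_spec(seed = 10))
  expect_identical(a1, a2)
  expect_false(identical(a1$images, a3$images))
  expect_error(augment_spec(factor = 0), ">= 1")
})

test_that("image folders load with per-class labels and validation", {
  root <- withr::local_tempdir()
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 24, seed = 4),
                                   c(QP = 2, PP = 2, BYP = 2, YYP = 2, IP = 2))
  write_image_folder(ds, root)
  loaded <- load_image_folder(root)
  expect_length(loaded$images, 10)
  expect_identical(as.integer(table(loaded$labels)), rep(2L, 5))
  # unknown subdirectory names the expected labels
  dir.create(file.path(root, "foo"))
  expect_error(load_image_folder(root), "QP.*PP.*BYP.*YYP.*IP")
  unlink(file.path(root, "foo"), recursive = TRUE)
  # corrupt file warns and is skipped
  writeLines("not a png", file.path(root, "QP", "broken.png"))
  expect_warning(l2 <- load_image_folder(root), "unreadable")
  expect_length(l2$images, 10)
})

test_that("an empty known class directory yields zero items with a warning", {
  root <- withr::local_tempdir()
  ds <- generate_synthetic_dataset(synthetic_egg_params(size = 24, seed = 5),
                                   c(QP = 2))
  write_image_folder(ds, root)
  dir.create(file.path(root, "IP"))
  expect_warning(loaded <- load_image_folder(root), "no images found for class IP")
  expect_identical(sum(loaded$labels == "IP"), 0L)
  expect_length(loaded$images, 2)
})

test_that("preprocessing resizes, crops and standardises", {
  img <- array(stats::runif(40 * 60 * 3), c(40, 60, 3))
  out <- preprocess_image(img, size = 32)
  expect_identical(dim(out), c(32L, 32L, 3L))
  st <- list(mean = c(0.5, 0.5, 0.5), sd = c(0.25, 0.25, 0.25))
  out2 <- preprocess_image(img, size = 32, stats = st)
  expect_equal(out2, (out - 0.5) / 0.25, tolerance = 1e-12)
  ds <- list(images = list(img))
  cs <- channel_stats(ds)
  for (ch in 1:3) expect_equal(cs$mean[ch], mean(img[, , ch]), tolerance = 1e-12)
})

test_that("grade mapping is the total surjection onto three grades", {
  g <- egg_grade(c("QP", "PP", "BYP", "YYP", "IP"))
  expect_identical(as.character(g), c("QP", "SP", "SP", "SP", "IP"))
  expect_identical(levels(g), egg_grades())
  expect_error(egg_grade("XX"), "unknown labels")
})
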