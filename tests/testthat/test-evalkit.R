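test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(1, 1, 2), c(1, 2, 2), labels = c("a", "b"))
  expect_identical(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 1L), 2,
                   dimnames = list(true = c("a", "b"), predicted = c("a", "b")))[, ])
  perfect <- confusion(egg_labels(), egg_labels())
  expect_identical(sum(diag(perfect)), 5L)
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  set.seed(1)
  truth <- sample(egg_labels(), 50, replace = TRUE)
  pred <- sample(egg_labels(), 50, replace = TRUE)
  expect_identical(sum(confusion(truth, pred)), 50L)
  expect_error(confusion(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(confusion(c(0, 1), c(1, 1), labels = c("a", "b")), "range")
})

test_that("accuracy, precision, recall and F1 match hand arithmetic", {
  cm <- structure(matrix(c(8L, 3L, 2L, 7L), 2,
                         dimnames = list(true = c("pos", "neg"),
                                         predicted = c("pos", "neg"))),
                  class = c("confusion_matrix", "matrix"))
  expect_equal(accuracy(cm), 15 / 20)
  expect_equal(precision(cm, 1), 8 / 11, tolerance = 1e-12)
  expect_equal(recall(cm, 1), 0.8)
  expect_equal(f1(cm, 1), 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8), tolerance = 1e-12)
  expect_equal(round(f1(cm, 1), 4), 0.7619)
  expect_equal(precision(cm, "pos"), precision(cm, 1))
})

test_that("a perfect classifier scores 1 everywhere", {
  cm <- confusion(egg_labels(), egg_labels())
  expect_equal(accuracy(cm), 1)
  for (i in 1:5) expect_equal(f1(cm, i), 1)
})

test_that("empty predicted classes yield 0 with a warning, not an error", {
  cm <- confusion(c("QP", "QP", "IP"), c("QP", "QP", "QP"))
  expect_warning(p <- precision(cm, "PP"), "zero denominator")
  expect_identical(p, 0)
  expect_warning(r <- recall(cm, "PP"), "zero denominator")
  expect_identical(r, 0)
})

test_that("metrics agree with a scalar TP/FP/FN oracle on random matrices", {
  for (s in 1:10) {
    cm <- rand_cm5(s)
    for (i in 1:5) {
      o <- metrics_scalar(cm, i)
      expect_equal(suppressWarnings(precision(cm, i)), o$precision, tolerance = 1e-12)
      expect_equal(suppressWarnings(recall(cm, i)), o$recall, tolerance = 1e-12)
      expect_equal(suppressWarnings(f1(cm, i)), o$f1, tolerance = 1e-12)
    }
    expect_equal(accuracy(cm), sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("grade consolidation conserves counts and moves mass to the diagonal", {
  for (s in 1:20) {
    cm5 <- rand_cm5(100 + s)
    cm3 <- consolidate_grades(cm5)
    expect_identical(sum(cm3), sum(cm5))
    # per-grade row sums equal the summed class row sums
    expect_identical(cm3["SP", "SP"],
                     sum(cm5[c("PP", "BYP", "YYP"), c("PP", "BYP", "YYP")]))
    expect_identical(sum(cm3["QP", ]), sum(cm5["QP", ]))
    expect_gte(accuracy(cm3), accuracy(cm5))
  }
})

test_that("within-substandard confusions become correct at grade level", {
  cm5 <- confusion("PP", "BYP")
  cm3 <- consolidate_grades(cm5)
  expect_identical(cm3["SP", "SP"], 1L)
  expect_equal(accuracy(cm3), 1)
  expect_equal(accuracy(cm5), 0)
})

test_that("consolidation requires the five-class label set", {
  cm <- confusion(c(1, 2), c(1, 2), labels = c("a", "b"))
  expect_error(consolidate_grades(cm), "QP, PP, BYP, YYP, IP")
})

test_that("reports carry per-class F1 percentages and accuracy", {
  cm <- rand_cm5(7)
  rep5 <- classification_report(cm, "demo", param_count = 20955653)
  expect_identical(rep5$Parameter, "21.0M")
  expect_identical(rep5[["Accuracy/%"]], round(100 * accuracy(cm), 1))
  expect_identical(rep5[["BYP Egg F1/%"]], round(100 * f1(cm, "BYP"), 1))
})
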