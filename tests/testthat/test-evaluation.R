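test_that("confusion matrix matches a per-pixel loop oracle", {
  set.seed(71)
  truth <- matrix(sample(0:4, 400, TRUE), 20, 20)
  pred <- matrix(sample(0:4, 400, TRUE), 20, 20)
  cm <- confusion(pred, truth)
  oracle <- matrix(0L, 5, 5)
  for (i in 1:20) for (j in 1:20) {
    oracle[truth[i, j] + 1, pred[i, j] + 1] <-
      oracle[truth[i, j] + 1, pred[i, j] + 1] + 1L
  }
  expect_identical(unclass(unname(cm)), oracle)
  expect_equal(unname(rowSums(normalize_confusion(cm))), rep(1, 5))
  expect_error(confusion(pred[1:10, ], truth), "dimensions")
})

test_that("perfect prediction gives a diagonal matrix and unit metrics", {
  truth <- matrix(sample(0:4, 100, TRUE), 10, 10)
  cm <- confusion(truth, truth)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  rep <- class_report(cm)
  present <- rep$support > 0
  expect_true(all(rep$precision[present] == 1 & rep$jaccard[present] == 1))
})

test_that("per-class metrics follow their definitions", {
  # TP = 1, FP = 1, FN = 1 for class a in a 2-class toy
  cm <- structure(matrix(c(1L, 1L, 1L, 7L), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  class = c("zq_confusion", "matrix"))
  rep <- class_report(cm)
  expect_equal(rep$precision[1], 0.5)
  expect_equal(rep$recall[1], 0.5)
  expect_equal(rep$f1[1], 0.5)
  expect_equal(rep$jaccard[1], 1 / 3)
})

test_that("zero-denominator metric cells are reported as 0", {
  cm <- structure(matrix(c(0L, 0L, 5L, 5L), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  class = c("zq_confusion", "matrix"))
  rep <- class_report(cm)
  expect_equal(rep$precision[1], 0)  # no predictions of class a
  expect_equal(rep$f1[1], 0)
})

test_that("Jaccard = F1/(2 - F1) holds exactly on random confusion matrices", {
  set.seed(12)
  for (i in 1:20) {
    cm <- matrix(rpois(25, 40), 5, 5,
                 dimnames = list(letters[1:5], letters[1:5]))
    rep <- class_report(structure(cm, class = c("zq_confusion", "matrix")))
    expect_equal(rep$jaccard, rep$f1 / (2 - rep$f1), tolerance = 1e-12)
  }
})

test_that("DICE/Jaccard conversions are mutual inverses", {
  d <- seq(0, 1, by = 0.01)
  expect_equal(dice_from_jaccard(jaccard_from_dice(d)), d, tolerance = 1e-12)
  expect_equal(jaccard_from_dice(1), 1)
  expect_equal(jaccard_from_dice(0), 0)
  expect_error(jaccard_from_dice(1.2))
})

test_that("aggregation conventions: macro mean, support weighting, exclusion", {
  rep <- reference_validation_report()
  m <- aggregate_report(rep, "macro")
  expect_equal(m$precision, mean(rep$precision))
  w <- aggregate_report(rep, "weighted")
  expect_equal(w$f1, weighted.mean(rep$f1, rep$support))
  # aggregate jaccard follows the F1-conversion convention by default
  expect_equal(w$jaccard, jaccard_from_dice(w$f1))
  # and the plain per-class mean as the alternative
  expect_equal(aggregate_report(rep, "macro", jaccard = "mean")$jaccard,
               mean(rep$jaccard))
  # excluding a class equals aggregating a report built without it
  sub <- rep[rep$class != "ignore", ]
  class(sub) <- class(rep)
  expect_equal(aggregate_report(rep, "weighted", exclude = "ignore"),
               aggregate_report(sub, "weighted"))
  expect_error(aggregate_report(rep, "macro", exclude = rep$class), "no classes")
})

test_that("zero-support classes are dropped from macro averages with warning", {
  rep <- report_rows(class = c("a", "b"), precision = c(0.5, 0),
                     recall = c(0.5, 0), f1 = c(0.5, 0),
                     support = c(10, 0))
  expect_warning(m <- aggregate_report(rep, "macro"), "zero-support")
  expect_equal(m$precision, 0.5)
})

test_that("background correction replaces precision and recomputes the row", {
  rep <- reference_validation_report()
  cor <- correct_background(rep, 0.980)
  i <- match("background", cor$class)
  expect_equal(cor$precision[i], 0.980)
  expect_equal(cor$recall[i], rep$recall[i])      # recall untouched
  expect_equal(cor$f1[i], 2 * 0.980 * cor$recall[i] / (0.980 + cor$recall[i]))
  expect_equal(cor$jaccard[i], jaccard_from_dice(cor$f1[i]))
  # substituting the original precision leaves a self-consistent report
  # (one built from counts, where F1 derives exactly from P and R) unchanged
  set.seed(77)
  cm <- matrix(rpois(25, 50), 5, 5,
               dimnames = list(zone_classes(), zone_classes()))
  rep2 <- class_report(structure(cm, class = c("zq_confusion", "matrix")))
  i2 <- match("background", rep2$class)
  same <- correct_background(rep2, rep2$precision[i2])
  expect_equal(same$f1, rep2$f1, tolerance = 1e-12)
  expect_error(correct_background(rep, 0), "0, 1")
  expect_error(correct_background(rep, 0.5, class = "nope"), "not present")
})

test_that("report rendering rounds to 3 decimals and keeps aggregate rows", {
  tab <- full_report_table(reference_validation_report())
  expect_equal(nrow(tab), 9)
  expect_true(all(abs(tab$f1 - round(tab$f1, 3)) < 1e-12))
  f <- tempfile(fileext = ".csv")
  write_report_csv(reference_validation_report(), f)
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), 9)
})
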