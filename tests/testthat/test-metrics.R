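test_that("confusion matrices count pairs with fixed label order", {
  cm <- build_confusion(c("a", "a", "b"), c("a", "b", "b"),
                        labels = c("a", "b"))
  expect_equal(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 1L), 2, 2,
               dimnames = list(true = c("a", "b"),
                               predicted = c("a", "b"))))
  ident <- build_confusion(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_true(all(ident[upper.tri(ident) | lower.tri(ident)] == 0))
  single <- build_confusion("x", "y", labels = c("x", "y"))
  expect_equal(single["x", "y"], 1L)
  expect_equal(sum(single), 1L)
  y <- sample(letters[1:3], 30, replace = TRUE)
  p <- sample(letters[1:3], 30, replace = TRUE)
  cm2 <- build_confusion(y, p, labels = letters[1:3])
  expect_equal(rowSums(cm2), table(factor(y, letters[1:3])),
               ignore_attr = TRUE)
  expect_error(build_confusion("a", "z", labels = c("a", "b")), "outside")
  expect_error(build_confusion(character(0), character(0)), "nonempty")
})

test_that("diagonal reconstruction preserves row totals and the diagonal", {
  cm <- confusion_from_diagonal(diag_epoch2000, class_totals_8,
                                labels = class_labels_8)
  expect_equal(as.numeric(diag(cm)), diag_epoch2000)
  expect_equal(as.numeric(rowSums(cm)), class_totals_8)
  expect_equal(sum(cm), sum(class_totals_8))
  expect_error(confusion_from_diagonal(c(5, 5), c(4, 6)), "lie in")
})

test_that("per-class one-vs-rest metrics match hand-computed counts", {
  cm <- confusion_from_diagonal(diag_epoch2000, class_totals_8,
                                labels = class_labels_8)
  per <- per_class_metrics(cm)
  # class A: TP = 89 of 106 true-A samples
  expect_equal(round(per$recall[per$class == "A"], 2), 83.96)
  expect_equal(round(per$recall[per$class == "DC"], 2), 98.86)
  # G-mean squared equals recall times specificity on unrounded values
  expect_equal(per$gmean^2, per$recall * per$specificity, tolerance = 1e-9)
  # a perfect two-class matrix scores 100 everywhere
  perfect <- build_confusion(rep(c("p", "q"), each = 5),
                             rep(c("p", "q"), each = 5))
  pp <- per_class_metrics(perfect)
  for (m in c("accuracy", "precision", "recall", "specificity", "fscore",
              "mcc", "gmean")) {
    expect_equal(pp[[m]], c(100, 100))
  }
})

test_that("MCC is bounded and reaches 100 only on diagonal matrices", {
  set.seed(12)
  for (i in 1:20) {
    y <- sample(letters[1:4], 40, replace = TRUE)
    p <- sample(letters[1:4], 40, replace = TRUE)
    per <- per_class_metrics(build_confusion(y, p, labels = letters[1:4]))
    expect_true(all(per$mcc >= -100 & per$mcc <= 100))
    if (any(per$mcc == 100)) {
      k <- which(per$mcc == 100)
      cm <- build_confusion(y, p, labels = letters[1:4])
      # one-vs-rest perfection: no off-diagonal mass in that class's row/col
      for (kk in k) {
        expect_equal(sum(cm[kk, ]) + sum(cm[, kk]), 2 * cm[kk, kk])
      }
    }
  }
})

test_that("degenerate classes report zero with a flag instead of erroring", {
  # class b never predicted: its precision denominator TP + FP is zero
  cm <- build_confusion(c("a", "a", "b", "c"), c("a", "a", "c", "c"),
                        labels = c("a", "b", "c"))
  per <- per_class_metrics(cm)
  expect_equal(per$precision[per$class == "b"], 0)
  expect_true(per$degenerate[per$class == "b"])
  expect_false(per$degenerate[per$class == "a"])
})

test_that("macro averaging is the unweighted mean and reporting rounds half-up", {
  cm <- confusion_from_diagonal(diag_epoch500, class_totals_8,
                                labels = class_labels_8)
  per <- per_class_metrics(cm)
  avg <- macro_average(per)
  expect_equal(avg$recall, mean(per$recall), tolerance = 1e-12)
  one <- macro_average(per[3, ])
  expect_equal(one$recall, per$recall[3])
  rep500 <- metrics_report(cm)
  expect_equal(rep500$recall[rep500$class == "Average"],
               macro_recall_epoch500)
  # overall accuracy is the trace share, complementing the error fitness
  expect_equal(overall_accuracy(cm), 100 * sum(diag(cm)) / sum(cm))
})

test_that("reports serialize to CSV and JSON and plot without error", {
  cm <- build_confusion(rep(c("a", "b"), each = 4),
                        c("a", "a", "a", "b", "b", "b", "b", "a"))
  rep <- metrics_report(cm)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_metrics(rep, csv)
  write_metrics(rep, js)
  back <- utils::read.csv(csv)
  expect_equal(back$recall, rep$recall)
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed), nrow(rep))
  expect_error(write_metrics(rep, tempfile(fileext = ".txt")), "csv")
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_confusion(cm), "ggplot")
})
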