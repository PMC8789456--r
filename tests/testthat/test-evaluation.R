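test_that("confusion matrices count truth-by-prediction pairs", {
  truth <- c("A", "A", "B", "C", "C", "C")
  cm <- confusion(truth, truth, classes = c("A", "B", "C"))
  expect_equal(diag(unclass(cm)), c(A = 2L, B = 1L, C = 3L))
  expect_equal(sum(unclass(cm)) - sum(diag(unclass(cm))), 0L)

  all_b <- confusion(truth, rep("B", 6), classes = c("A", "B", "C"))
  expect_equal(unname(colSums(unclass(all_b))), c(0L, 6L, 0L))

  set.seed(2)
  t2 <- sample(c("A", "B", "C"), 40, replace = TRUE)
  p2 <- sample(c("A", "B", "C"), 40, replace = TRUE)
  cm2 <- confusion(t2, p2, classes = c("A", "B", "C"))
  expect_equal(unname(rowSums(unclass(cm2))), as.integer(table(factor(t2, c("A", "B", "C")))))

  expect_error(confusion(c("A", "Z"), c("A", "A"), classes = c("A", "B")), "unknown")
})

test_that("per-class metrics reproduce the published run-1 arithmetic", {
  # correct counts 19/24, 64/72, 12/18, 170/171, 54/56 for IVT, IPC, SAD,
  # EPI, SBD; off-diagonal placement does not affect sensitivity
  correct <- c(19, 64, 12, 170, 54)
  totals <- c(24, 72, 18, 171, 56)
  sens <- sensitivity_from_counts(correct, totals, ich_classes)
  expect_equal(round(sens$sensitivity[1:5], 4), c(0.7917, 0.8889, 0.6667, 0.9942, 0.9643))
  expect_equal(round(sens$sensitivity[6], 4), 0.8611)
})

test_that("a perfect diagonal gives all metrics 1", {
  truth <- rep(c("A", "B"), times = c(5, 7))
  cm <- confusion(truth, truth)
  m <- per_class_metrics(cm)
  expect_true(all(abs(as.matrix(m[, c("sensitivity", "specificity", "precision", "accuracy")]) - 1) < 1e-12))
  expect_false(any(m$degenerate))
})

test_that("metrics match an independent TP/FP/FN/TN recomputation", {
  set.seed(9)
  classes <- paste0("k", 1:5)
  truth <- sample(classes, 120, replace = TRUE)
  pred <- sample(classes, 120, replace = TRUE)
  cm <- confusion(truth, pred, classes)
  m <- per_class_metrics(cm)
  for (cl in classes) {
    TP <- sum(truth == cl & pred == cl)
    FN <- sum(truth == cl & pred != cl)
    FP <- sum(truth != cl & pred == cl)
    TN <- sum(truth != cl & pred != cl)
    row <- m[m$class == cl, ]
    expect_equal(row$sensitivity, TP / (TP + FN))
    expect_equal(row$specificity, TN / (TN + FP))
    expect_equal(row$precision, if (TP + FP == 0) 0 else TP / (TP + FP))
    expect_equal(row$accuracy, (TP + TN) / 120)
  }
})

test_that("macro averages are unweighted means and reproduce the published rows", {
  sens1 <- c(19 / 24, 64 / 72, 12 / 18, 170 / 171, 54 / 56)
  expect_equal(round(mean(sens1), 4), 0.8611)
  sens3 <- c(22 / 24, 64 / 72, 12 / 18, 170 / 171, 54 / 56)
  expect_equal(round(mean(sens3), 4), 0.8861)
  # single class: average equals the class value
  cm <- confusion(c("A", "A"), c("A", "A"), classes = "A")
  m <- per_class_metrics(cm)
  expect_equal(macro_average(m)$sensitivity, m$sensitivity)
})

test_that("per-class one-vs-rest accuracy matches the published definition", {
  # run-1 IVT: TP = 19, FN = 5, FP = 6 (precision 0.76), TN = 311 -> 330/341
  cm <- matrix(0L, 5, 5, dimnames = list(truth = ich_classes, predicted = ich_classes))
  diag(cm) <- c(19L, 64L, 12L, 170L, 54L)
  cm["IVT", "IPC"] <- 5L   # 24 IVT total
  cm["IPC", "IVT"] <- 6L   # 6 false positives into IVT
  cm["IPC", "EPI"] <- 2L   # 72 IPC total
  cm["SAD", "EPI"] <- 6L   # 18 SAD total
  cm["EPI", "SBD"] <- 1L   # 171 EPI total
  cm["SBD", "EPI"] <- 2L   # 56 SBD total
  cmx <- structure(cm, class = c("confusion_matrix", "matrix"))
  m <- per_class_metrics(cmx)
  expect_equal(sum(unclass(cmx)), 341L)
  ivt <- m[m$class == "IVT", ]
  expect_equal(round(ivt$sensitivity, 4), 0.7917)
  expect_equal(round(ivt$precision, 4), 0.76)
  expect_equal(round(ivt$accuracy, 4), 0.9677)
})

test_that("metric invariants hold: trace, totals, and two-class duality", {
  set.seed(4)
  truth <- sample(c("A", "B"), 60, replace = TRUE)
  pred <- sample(c("A", "B"), 60, replace = TRUE)
  cm <- confusion(truth, pred, c("A", "B"))
  m <- per_class_metrics(cm)
  expect_equal(sum(diag(unclass(cm))), sum(truth == pred))
  expect_equal(sum(unclass(cm)), 60L)
  # class-A sensitivity equals class-B specificity for two classes
  expect_equal(m$sensitivity[m$class == "A"], m$specificity[m$class == "B"])
  # permuting the class order permutes but does not change metric values
  cm2 <- confusion(truth, pred, c("B", "A"))
  m2 <- per_class_metrics(cm2)
  expect_equal(m$sensitivity[m$class == "A"], m2$sensitivity[m2$class == "A"])
})

test_that("degenerate denominators yield zero with a flag", {
  cm <- confusion(c("A", "A"), c("A", "A"), classes = c("A", "B"))
  m <- per_class_metrics(cm)
  b <- m[m$class == "B", ]
  expect_equal(b$sensitivity, 0)
  expect_true(b$degenerate)
})

test_that("report tables round half-even to four decimals and append an Average row", {
  cm <- confusion(rep(c("A", "B"), c(3, 3)), c("A", "A", "B", "B", "B", "B"), c("A", "B"))
  rep_tbl <- metric_report(cm)
  expect_equal(rep_tbl$class, c("A", "B", "Average"))
  expect_equal(rep_tbl$sensitivity[1], round(2 / 3, 4))
})
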