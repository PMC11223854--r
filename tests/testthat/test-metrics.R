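test_that("confusion counts follow the four definitions", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unclass(c1)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  c2 <- confusion(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_identical(c(c2$TP, c2$TN), c(0L, 0L))

  withr::with_seed(3, {
    for (rep in 1:25) {
      n <- sample(5:60, 1)
      pred <- sample(0:1, n, replace = TRUE)
      truth <- sample(0:1, n, replace = TRUE)
      cc <- confusion(pred, truth)
      expect_identical(cc$TP, sum(pred == 1 & truth == 1))
      expect_identical(cc$FP, sum(pred == 1 & truth == 0))
      expect_identical(cc$FN, sum(pred == 0 & truth == 1))
      expect_identical(cc$TN, sum(pred == 0 & truth == 0))
      expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, n)
    }
  })
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "differ in length")
})

test_that("precision, recall and specificity are the three tally ratios", {
  m <- precision_recall_specificity(list(TP = 3, FP = 1, FN = 1, TN = 5))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 5 / 6)

  perfect <- precision_recall_specificity(list(TP = 4, FP = 0, FN = 0, TN = 6))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, specificity = 1))

  expect_warning(
    und <- precision_recall_specificity(list(TP = 0, FP = 0, FN = 2, TN = 3)),
    "precision undefined")
  expect_true(is.na(und$precision))
  expect_equal(und$recall, 0)
})

test_that("ROC AUC equals the pairwise ordering statistic on random instances", {
  rc <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(rc, "auc"), 0.75)
  expect_true(all(diff(rc$fpr) >= 0))

  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(perfect, "auc"), 1)
  flat <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(attr(flat, "auc"), 0.5)

  withr::with_seed(5, {
    for (rep in 1:50) {
      n <- sample(4:50, 1)
      truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
      expect_lt(abs(attr(roc_curve(scores, truth), "auc") -
                      oracle_auc_pairwise(scores, truth)), 1e-12)
    }
  })
  expect_error(roc_curve(runif(4), rep(1, 4)), "both classes")
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- 40
      truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
      ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(attr(roc_curve(scores, truth), "auc"), ref,
                   tolerance = 1e-12)
    }
  })
})

test_that("PR AUC follows non-interpolated step summation", {
  perfect <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(perfect, "auc"), 1)

  flat <- pr_curve(rep(0.3, 10), rep(c(1, 0), c(3, 7)))
  expect_equal(attr(flat, "auc"), 0.3)  # prevalence

  withr::with_seed(9, {
    for (rep in 1:30) {
      n <- sample(4:40, 1)
      truth <- c(1, sample(0:1, n - 1, replace = TRUE))
      scores <- round(runif(n), 2)
      expect_lt(abs(attr(pr_curve(scores, truth), "auc") -
                      oracle_pr_auc(scores, truth)), 1e-12)
    }
  })
  expect_error(pr_curve(runif(3), c(0, 0, 0)), "at least one positive")
})

test_that("Youden threshold maximizes J and matches exhaustive search", {
  # perfect separator: J = 1 at the smallest qualifying threshold
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  yt <- youden_threshold(rc)
  expect_equal(yt$J, 1)
  expect_equal(yt$threshold, 0.8)

  flat <- youden_threshold(roc_curve(rep(0.5, 6), rep(c(1, 0), 3)))
  expect_equal(flat$J, 0)

  scores <- c(0.9, 0.8, 0.4, 0.5, 0.3, 0.1)
  truth <- c(1, 1, 1, 0, 0, 0)
  yt2 <- youden_threshold(roc_curve(scores, truth))
  or <- oracle_youden(scores, truth)
  expect_equal(yt2$J, or$J, tolerance = 1e-12)
  expect_true(list(as.integer(scores >= yt2$threshold)) %in% or$label_sets)
})
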