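test_that("stratified split puts round(fraction * n_class) of each class in train", {
  labels <- rep(c(1, 0), c(30, 70))
  sp <- stratified_split(labels, 0.9, seed = 4)
  expect_identical(sum(labels[sp$train_indices] == 1), 27L)
  expect_identical(sum(labels[sp$train_indices] == 0), 63L)
  expect_identical(sort(c(sp$train_indices, sp$test_indices)), 1:100)
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
})

test_that("round-half-even applies to the class counts of the full hexapeptide set", {
  # 515 amyloid / 901 non-amyloid at fraction 0.9: round(463.5) = 464 under
  # round-half-even, so the test split keeps 51 positives and 90 negatives
  labels <- rep(c(1, 0), c(515, 901))
  sp <- stratified_split(labels, 0.9, seed = 1)
  expect_identical(sum(labels[sp$test_indices] == 1), 51L)
  expect_identical(sum(labels[sp$test_indices] == 0), 90L)
})

test_that("splits are deterministic under seed and validate input", {
  labels <- rep(c(1, 0), c(20, 30))
  expect_identical(stratified_split(labels, 0.8, seed = 9),
                   stratified_split(labels, 0.8, seed = 9))
  expect_error(stratified_split(rep(1, 10), 0.9, seed = 1), "both classes")
  expect_error(stratified_split(labels, 1.0, seed = 1), "inside \\(0, 1\\)")
  expect_error(stratified_split(labels, 0, seed = 1), "inside \\(0, 1\\)")
  expect_error(stratified_split(numeric(0), 0.9, seed = 1), "nonempty|both classes")
})

test_that("fold assignment partitions indices with near-equal stratified folds", {
  labels <- rep(c(1, 0), c(25, 25))
  fp <- make_folds(labels, k = 5, seed = 2)
  expect_identical(sort(unique(fp$fold_assignments)), 1:5)
  for (f in 1:5) {
    expect_identical(sum(fp$fold_assignments == f & labels == 1), 5L)
    expect_identical(sum(fp$fold_assignments == f & labels == 0), 5L)
  }

  withr::with_seed(6, {
    for (rep in 1:20) {
      n_pos <- sample(6:40, 1)
      n_neg <- sample(6:60, 1)
      labs <- sample(rep(c(1, 0), c(n_pos, n_neg)))
      fp2 <- make_folds(labs, k = 5, seed = rep)
      expect_length(fp2$fold_assignments, n_pos + n_neg)
      for (cls in 0:1) {
        per_fold <- table(factor(fp2$fold_assignments[labs == cls],
                                 levels = 1:5))
        expect_lte(max(per_fold) - min(per_fold), 1)
      }
    }
  })
  expect_identical(make_folds(labels, 5, seed = 3),
                   make_folds(labels, 5, seed = 3))
  expect_error(make_folds(rep(c(1, 0), c(3, 50)), k = 5, seed = 1),
               "minority class")
})

test_that("the stopping rule returns the best-validation epoch before the stall", {
  expect_identical(select_stopping_epoch(c(0.6, 0.7, 0.7, 0.69, 0.68),
                                         patience = 2, min_delta = 0), 2L)
  expect_identical(select_stopping_epoch(seq(0.5, 0.9, by = 0.1),
                                         patience = 2, min_delta = 0), 5L)
  expect_identical(select_stopping_epoch(rep(0.8, 10), patience = 3,
                                         min_delta = 0.001), 1L)
  expect_error(select_stopping_epoch(numeric(0)), "nonempty")

  # property: the chosen epoch is the running maximum of the history prefix
  withr::with_seed(11, {
    for (rep in 1:30) {
      val <- runif(sample(3:40, 1), 0.5, 1)
      e <- select_stopping_epoch(val, patience = 4, min_delta = 0.005)
      expect_equal(val[e], max(val[1:e]))
      expect_true(all(val[seq_len(e - 1)] <= val[e]))
    }
  })
})
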