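test_that("forward-chaining splits partition the tail without leakage", {
  plan <- forward_chain_splits(12, 5)
  starts <- vapply(plan$splits, function(s) min(s$test), 0L)
  sizes <- vapply(plan$splits, function(s) length(s$test), 0L)
  expect_equal(starts, c(3L, 5L, 7L, 9L, 11L))
  expect_equal(sizes, rep(2L, 5))
  for (sp in plan$splits) {
    expect_lt(max(sp$train), min(sp$test))
    expect_equal(sp$train, seq_len(min(sp$test) - 1L))
  }
  all_test <- sort(unlist(lapply(plan$splits, `[[`, "test")))
  expect_equal(all_test, 3:12)                   # disjoint tail partition
  expect_equal(anyDuplicated(all_test), 0L)

  # remainder goes to the earlier folds
  plan13 <- forward_chain_splits(13, 5)
  expect_equal(vapply(plan13$splits, function(s) length(s$test), 0L),
               c(3L, 2L, 2L, 2L, 2L))
  # successive training sets are supersets
  trains <- lapply(plan13$splits, `[[`, "train")
  for (k in 2:5) expect_true(all(trains[[k - 1]] %in% trains[[k]]))

  expect_error(forward_chain_splits(5, 5), class = "phyto_config_error")
})

test_that("per-fold standardisation uses training statistics only", {
  set.seed(20)
  tr <- matrix(rnorm(60, 5, 3), 20, 3)
  te <- matrix(rnorm(15, 5, 3), 5, 3)
  std <- standardize_per_fold(tr, te)
  expect_equal(unname(colMeans(std$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(std$train^2))), rep(1, 3), tolerance = 1e-12)
  # a test row equal to the training mean standardises to zero
  std2 <- standardize_per_fold(tr, matrix(colMeans(tr), 1))
  expect_equal(as.numeric(std2$test), rep(0, 3), tolerance = 1e-12)
  # re-standardising standardised data is the identity
  std3 <- standardize_per_fold(std$train, std$test)
  expect_equal(std3$train, std$train, tolerance = 1e-12)
  expect_equal(std3$test, std$test, tolerance = 1e-12)
  # constant columns pass through centred with a warning
  trc <- cbind(tr, 7)
  expect_warning(stdc <- standardize_per_fold(trc, cbind(te, 7)), "constant")
  expect_equal(unname(stdc$train[, 4]), rep(0, 20))
})

test_that("balanced accuracy follows the per-class recall definition", {
  cm_valence <- matrix(c(67, 31, 11, 71), 2,
                       dimnames = list(c("0", "1"), c("0", "1")))
  expect_equal(balanced_accuracy(cm_valence), 0.5 * (67 / 78 + 71 / 102),
               tolerance = 1e-12)
  expect_equal(round(balanced_accuracy(cm_valence), 3), 0.778)
  expect_equal(balanced_accuracy(diag(c(5, 9, 3))), 1)
  # predicting one class always on balanced classes is chance
  cm1 <- matrix(c(50, 50, 0, 0), 2)
  expect_equal(balanced_accuracy(cm1), 0.5)
  # invariant to duplicating all samples of one class
  cm <- matrix(c(40, 10, 20, 30), 2)
  cm_dup <- cm; cm_dup[2, ] <- 3 * cm_dup[2, ]
  expect_equal(balanced_accuracy(cm), balanced_accuracy(cm_dup))
  # empty true classes are excluded with a warning
  cm0 <- matrix(c(10, 0, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(ba <- balanced_accuracy(cm0), "excluded")
  expect_equal(ba, 10 / 15)
})

test_that("F1 scores match the printed-table arithmetic and conventions", {
  cm_arousal <- matrix(c(656, 546, 344, 889), 2,
                       dimnames = list(c("0", "1"), c("0", "1")))
  f1 <- f1_scores(cm_arousal)
  expect_equal(unname(f1$per_class["1"]), 2 * 889 / (2 * 889 + 344 + 546),
               tolerance = 1e-12)
  expect_equal(round(unname(f1$per_class["1"]), 3), 0.666)
  expect_equal(f1$macro, mean(f1$per_class))
  expect_equal(f1_scores(diag(c(4, 4)))$per_class, c(`1` = 1, `2` = 1),
               ignore_attr = TRUE)
  # class never predicted and never correct scores 0 by convention
  cm <- matrix(c(10, 5, 0, 0), 2)
  expect_equal(unname(f1_scores(cm)$per_class[2]), 0)
})

test_that("majority baselines reproduce the printed class counts", {
  expect_equal(round(majority_baseline(c(108, 111)), 2), 0.51)
  expect_equal(majority_baseline(c(108, 111)), 111 / 219, tolerance = 1e-12)
  expect_equal(round(majority_baseline(c(1103, 1823)), 2), 0.62)
  expect_equal(majority_baseline(c(1103, 1823)), 1823 / 2926, tolerance = 1e-12)
  expect_equal(majority_baseline(42), 1)
  expect_error(majority_baseline(integer(0)), class = "phyto_degenerate_error")
})

test_that("fully predictive features reach ceiling and independent ones stay at chance", {
  wt <- toy_window_table(n = 150, informative = TRUE, seed = 21)
  rep_v <- evaluate_pipeline(wt, "valence")
  expect_true(all(rep_v$folds$balanced_accuracy > 0.95))
  rep_a <- evaluate_pipeline(wt, "arousal")
  expect_true(all(rep_a$folds$balanced_accuracy > 0.95))

  ba_null <- vapply(1:20, function(s) {
    wt0 <- toy_window_table(n = 150, informative = FALSE, seed = 100 + s)
    evaluate_pipeline(wt0, "valence")$pooled$balanced_accuracy
  }, 0)
  expect_gt(mean(ba_null), 0.45)
  expect_lt(mean(ba_null), 0.55)
})

test_that("the pooled confusion accounts for every retained test window", {
  wt <- toy_window_table(n = 123, seed = 22)
  rep <- evaluate_pipeline(wt, "quadrant")
  n_test <- sum(rep$folds$n_test)
  expect_equal(sum(rep$pooled$confusion), n_test)
  expect_equal(dim(rep$pooled$confusion), c(4, 4))
  # binary macro-F1 equals the mean of the two per-class F1s
  rep_b <- evaluate_pipeline(wt, "valence")
  f1 <- f1_scores(rep_b$pooled$confusion)
  expect_equal(rep_b$pooled$macro_f1, mean(f1$per_class))
})

test_that("the ESN decoder path is deterministic end to end", {
  wt <- toy_window_table(n = 140, seed = 23)
  cfg <- reservoir_config(n_units = 50, washout = 10, seed = 24)
  r1 <- evaluate_pipeline(wt, "quadrant", "esn", reservoir = cfg)
  r2 <- evaluate_pipeline(wt, "quadrant", "esn", reservoir = cfg)
  expect_identical(r1, r2)
  expect_gt(r1$mean["balanced_accuracy"], 0.5)
})

test_that("environmental channels are refused as decoder features", {
  wt <- toy_window_table(n = 60, seed = 25)
  attr(wt, "feature_cols") <- c(attr(wt, "feature_cols"), "temperature_mean")
  expect_error(evaluate_pipeline(wt, "valence"), class = "phyto_config_error")
})

test_that("single-class inputs are degenerate, not silently scored", {
  wt <- toy_window_table(n = 80, seed = 26)
  wt$label_v <- 1L
  expect_error(evaluate_pipeline(wt, "valence"), class = "phyto_degenerate_error")
})
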