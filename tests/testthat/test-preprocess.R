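test_that("detect_outliers implements the strict 3-sigma rule", {
  expect_equal(sum(detect_outliers(rep(5, 10))), 0)        # sigma = 0 edge
  x <- c(rep(0, 100), 10)
  expect_identical(which(detect_outliers(x)), 101L)        # only the spike
  # value exactly at mean + k*sigma is NOT flagged (strict inequality)
  expect_equal(sum(detect_outliers(c(-1, 1), sigma_mult = 1)), 0)
  expect_error(detect_outliers(c(NA_real_, NA_real_, 1)), "finite")
  # NA entries are not flagged
  expect_false(any(detect_outliers(c(rep(0, 50), NA, 100))[51]))
})

test_that("impute_median fills with the supplied (training) median", {
  expect_equal(impute_median(c(1, NA, 3), 2), c(1, 2, 3))
  expect_equal(impute_median(c(1, 2, 3), 99), c(1, 2, 3))  # identity
  # idempotent
  once <- impute_median(c(1, NA, 3), 2)
  expect_identical(impute_median(once, 2), once)
  expect_error(impute_median(c(1, NA), NA_real_), "finite")
})

test_that("zscore matches direct evaluation and inverts", {
  out <- zscore(c(2, 4, 6), 4, sqrt(mean((c(2, 4, 6) - 4)^2)))
  expect_equal(out, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  x <- rnorm(50, 7, 3)
  z <- zscore(x, mean(x), sd(x))
  expect_lt(max(abs(z * sd(x) + mean(x) - x)), 1e-9)       # round trip
  expect_equal(zscore(rep(4, 5), 4, 2), rep(0, 5))
  expect_error(zscore(1:3, 0, 0), "positive")
})

test_that("onehot collapses rare and unseen categories into Others", {
  train <- c(rep("A", 50), rep("B", 30), rep("C", 5))
  blk <- onehot(train, threshold = 20)
  expect_setequal(names(blk), c("dx_A", "dx_B", "dx_Others"))
  expect_equal(blk$dx_Others[train == "C"], rep(1L, 5))
  expect_true(all(rowSums(blk) == 1))
  # unseen test category maps to Others using the training map
  lm <- attr(blk, "levels_map")
  test_blk <- onehot(c("A", "ZZZ"), levels_map = lm)
  expect_equal(test_blk$dx_Others, c(0L, 1L))
  # threshold 0: one column per observed category (plus empty Others)
  blk0 <- onehot(c("a", "b"), threshold = 0)
  expect_true(all(c("dx_a", "dx_b") %in% names(blk0)))
  expect_true(all(rowSums(blk0) == 1))
})

test_that("split_train_test produces the documented partition", {
  tab <- data.frame(id = seq_len(2495), niv_failure = rep_len(0:1, 2495))
  sp <- split_train_test(tab, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 1996)
  expect_equal(nrow(sp$test), 499)
  expect_setequal(c(sp$train$id, sp$test$id), tab$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)

  sp2 <- split_train_test(data.frame(x = 1:10, niv_failure = rep(0:1, 5)), 0.5, 7)
  expect_equal(nrow(sp2$train), 5)
  expect_identical(split_train_test(tab, 0.8, 1)$train$id, sp$train$id)
  expect_error(split_train_test(tab[1, , drop = FALSE], 0.5), "2 rows")

  strat <- split_train_test(tab, 0.8, 1, stratify = TRUE)
  expect_equal(sum(strat$train$niv_failure),
               round(0.8 * sum(tab$niv_failure)))
})

test_that("fitted preprocessor learns on train only and replays bit-for-bit", {
  set.seed(8)
  train <- data.frame(a = c(rnorm(50, 10, 2), 60), b = rnorm(51, -5, 1),
                      niv_failure = rep_len(0:1, 51))
  train$b[3] <- NA
  fp <- fit_preprocessor(train, preprocess_spec(),
                         numeric_cols = c("a", "b"), categorical_cols = NULL)
  out1 <- apply_preprocessor(fp, train)
  expect_identical(out1, apply_preprocessor(fp, train))    # reproducible
  expect_false(anyNA(out1$a))

  # test rows imputed with the TRAINING median, not their own
  test <- data.frame(a = c(NA, 11), b = c(-5, NA), niv_failure = 0:1)
  out2 <- apply_preprocessor(fp, test)
  med_a <- fp$numeric$a$median
  expect_equal(out2$a[1],
               zscore(med_a, fp$numeric$a$center, fp$numeric$a$scale))

  # fitted statistics do not depend on any test data by construction:
  # the training outlier (60) was masked before the median was taken
  expect_lt(fp$numeric$a$median, 15)
  expect_error(apply_preprocessor(fp, test[, "b", drop = FALSE]), "a")
})

test_that("zero-variance features are dropped with a warning", {
  train <- data.frame(a = rnorm(30), k = rep(3, 30), niv_failure = rep_len(0:1, 30))
  expect_warning(
    fp <- fit_preprocessor(train, numeric_cols = c("a", "k"),
                           categorical_cols = NULL),
    "zero-variance")
  expect_false("k" %in% names(fp$numeric))
  expect_true("k" %in% fp$dropped)
})
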