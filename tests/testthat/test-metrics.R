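test_that("confusion counts the four cells", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_equal(confusion(c(1, 0), c(1, 0))$FP + confusion(c(1, 0), c(1, 0))$FN, 0)
  inv <- confusion(c(1, 0), c(0, 1))
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion(c(1, 0), c(1)), "length")

  # independent tally on random vectors
  set.seed(1)
  for (r in 1:20) {
    yt <- rbinom(30, 1, 0.5); yp <- rbinom(30, 1, 0.5)
    cm <- confusion(yt, yp)
    expect_equal(cm$TP, sum(yt & yp))
    expect_equal(cm$TN, sum(!yt & !yp))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 30)
  }
})

test_that("accuracy/precision/recall follow their formulas and conventions", {
  cm <- structure(list(TP = 3, FP = 1, FN = 2, TN = 4), class = "niv_confusion")
  expect_equal(accuracy(cm), 0.7)
  expect_equal(precision(cm), 0.75)
  expect_equal(recall(cm), 0.6)
  perfect <- structure(list(TP = 1, FP = 0, FN = 0, TN = 1),
                       class = "niv_confusion")
  expect_equal(c(accuracy(perfect), precision(perfect), recall(perfect)),
               c(1, 1, 1))
  nopos <- structure(list(TP = 0, FP = 0, FN = 2, TN = 5),
                     class = "niv_confusion")
  expect_warning(p <- precision(nopos), "zero denominator")
  expect_equal(p, 0)
})

test_that("f1 is the harmonic mean with the documented identity", {
  expect_equal(f1(0.5, 0.5), 0.5)             # equal inputs
  expect_equal(f1(0, 0), 0)                   # convention
  # Eq-based f1 equals 2TP/(2TP+FP+FN) from the confusion matrix
  set.seed(2)
  for (r in 1:50) {
    yt <- rbinom(40, 1, 0.4); yp <- rbinom(40, 1, 0.4)
    cm <- confusion(yt, yp)
    p <- suppressWarnings(precision(cm)); rc <- suppressWarnings(recall(cm))
    direct <- if (2 * cm$TP + cm$FP + cm$FN == 0) 0 else
      2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN)
    expect_lt(abs(f1(p, rc) - direct), 1e-12)
  }
})

test_that("roc_auc equals the pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "classes")

  brute <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(3)
  for (r in 1:30) {
    y <- c(0, 1, rbinom(18, 1, 0.5))
    s <- round(runif(20), 1)          # coarse grid forces ties
    expect_equal(roc_auc(y, s), brute(y, s))
  }
  # rank statistic: invariant under strictly increasing transforms
  y <- rbinom(50, 1, 0.5); y[1:2] <- 0:1
  s <- rnorm(50)
  expect_equal(roc_auc(y, s), roc_auc(y, exp(s)))
  expect_equal(roc_auc(y, s), roc_auc(y, qlogis(plogis(s))))
})

test_that("benchmark harnesses are deterministic and recomposable", {
  tab <- generate_cohort(cohort_spec(n_patients = 300, failure_rate = 0.25,
                                     missing_rate = 0, outlier_rate = 0,
                                     seed = 4))
  z <- std_split(tab, seed = 5)
  res <- benchmark_oversamplers(z$train_X, z$train_y, z$test_X, z$test_y,
                                methods = c("none", "modified"),
                                spec = oversample_spec(seed = 6), seed = 7)
  expect_equal(nrow(res), 2)
  expect_setequal(res$id, c("none", "modified"))
  res2 <- benchmark_oversamplers(z$train_X, z$train_y, z$test_X, z$test_y,
                                 methods = c("none", "modified"),
                                 spec = oversample_spec(seed = 6), seed = 7)
  expect_identical(res, res2)

  # recomposition: the "none" row equals a manual logistic fit + metrics
  lr <- learner_logistic()
  m <- lr$fit(z$train_X, z$train_y, seed = 7)
  manual <- metrics_row(z$test_y, lr$predict_proba(m, z$test_X), id = "none")
  expect_equal(res[res$id == "none", ], manual, ignore_attr = TRUE)

  one <- benchmark_classifiers(z$train_X, z$train_y, z$test_X, z$test_y,
                               learners = list(lr = learner_logistic()),
                               include_stack = FALSE, seed = 8)
  expect_equal(nrow(one), 1)
  expect_true(all(unlist(one[, -1]) >= 0 & unlist(one[, -1]) <= 1))
})
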