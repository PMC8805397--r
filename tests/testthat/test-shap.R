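test_that("linear explainer matches the closed form beta * (x - mean)", {
  set.seed(1)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(X[, 1] + 0.2 * rnorm(100) > 0)
  m <- learner_logistic()$fit(X, y)
  ex <- explain_instance(m, X[7, ], X)
  cf <- coef(m)
  expect_equal(unname(ex$attributions["a"]),
               unname(cf["a"] * (X[7, "a"] - mean(X[, "a"]))), tolerance = 1e-9)
  # additivity in link space
  eta <- as.numeric(cf[1] + X[7, ] %*% cf[-1])
  expect_lt(abs(ex$base_value + sum(ex$attributions) - eta), 1e-9)
  expect_equal(ex$prediction, eta, tolerance = 1e-9)

  # a feature the model cannot use (constant -> NA coefficient) gets 0
  X2 <- cbind(X, cnst = 1)
  m2 <- learner_logistic()$fit(X2, y)
  gi <- explain_global(m2, as.data.frame(X2), max_rows = 20)
  expect_equal(gi$importance[gi$feature == "cnst"], 0)
})

test_that("tree explainer equals brute-force Shapley on a small tree", {
  set.seed(5)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rnorm(60) + 2 * X[, 1] + (X[, 2] > 0)
  tr <- nivstack:::cart_build(X, y, 0:59, 3L, 5L, 3L, 11L)

  vfun <- function(tree, x, S) {
    rec <- function(node) {
      f <- tree$feature[node]
      if (f < 0) return(tree$value[node])
      l <- tree$left[node] + 1; r <- tree$right[node] + 1
      if ((f + 1) %in% S) {
        if (x[f + 1] <= tree$threshold[node]) rec(l) else rec(r)
      } else (tree$cover[l] * rec(l) + tree$cover[r] * rec(r)) / tree$cover[node]
    }
    rec(1)
  }
  brute <- function(tree, x, p = 3) {
    phi <- numeric(p)
    for (j in 1:p) {
      others <- setdiff(1:p, j)
      for (k in 0:length(others)) {
        Ss <- if (k == 0) list(integer(0)) else combn(others, k, simplify = FALSE)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        for (S in Ss) phi[j] <- phi[j] + w * (vfun(tree, x, c(S, j)) - vfun(tree, x, S))
      }
    }
    phi
  }
  for (i in 1:8)
    expect_lt(max(abs(nivstack:::tree_shap_one(tr, X[i, ]) - brute(tr, X[i, ]))),
              1e-9)
})

test_that("tree-model explanations are exactly additive", {
  d <- make_overlap_data(n = 250, sep = 2, seed = 2)
  gb <- learner_gbdt(n_trees = 30)$fit(d$X, d$y, seed = 3)
  rf <- learner_random_forest(n_trees = 25)$fit(d$X, d$y, seed = 3)
  rf_pred <- learner_random_forest()$predict_proba
  for (i in 1:15) {
    exg <- explain_instance(gb, d$X[i, , drop = FALSE], d$X)
    expect_lt(abs(exg$base_value + sum(exg$attributions) -
                    nivstack:::gbdt_margin(gb, d$X[i, , drop = FALSE])), 1e-6)
    exr <- explain_instance(rf, d$X[i, , drop = FALSE], d$X)
    expect_lt(abs(exr$base_value + sum(exr$attributions) -
                    rf_pred(rf, d$X[i, , drop = FALSE])), 1e-6)
  }
  # constant response: a single no-split tree attributes nothing
  cst <- learner_gbdt(n_trees = 1)$fit(d$X, rep(0L, nrow(d$X)), seed = 1)
  exc <- explain_instance(cst, d$X[1, , drop = FALSE], d$X)
  expect_true(all(abs(exc$attributions) < 1e-12))
})

test_that("stack sampling explainer is additive and seeded", {
  d <- make_overlap_data(n = 150, sep = 2, seed = 4)
  st <- fit_stack(d$X, d$y,
                  stack_spec(learners = default_learners(15L, 15L), seed = 5))
  ex <- explain_instance(st, d$X[3, , drop = FALSE], d$X, nsim = 5,
                         n_background = 10, seed = 6)
  pr <- predict_proba(st, d$X[3, , drop = FALSE])
  expect_lt(abs(ex$base_value + sum(ex$attributions) - pr), 1e-6)
  ex2 <- explain_instance(st, d$X[3, , drop = FALSE], d$X, nsim = 5,
                          n_background = 10, seed = 6)
  expect_identical(ex$attributions, ex2$attributions)
})

test_that("a dominant generated effect ranks first and signs cohere", {
  tab <- generate_cohort(cohort_spec(
    n_patients = 800, effect_sizes = c(rr = 2), missing_rate = 0,
    outlier_rate = 0, seed = 7))
  z <- std_split(tab, seed = 8)
  gb <- learner_gbdt(n_trees = 40)$fit(z$train_X, z$train_y, seed = 9)
  gi <- explain_global(gb, as.data.frame(z$train_X), max_rows = 40)
  # the only configured effect is at H1 RR; engineered from it are none here
  expect_equal(gi$feature[1], "H1_rr")

  # sign coherence: high RR pushes predictions toward failure
  idx <- which(z$train_X[, "H1_rr"] > quantile(z$train_X[, "H1_rr"], 0.7))[1:25]
  attr_sum <- 0
  for (i in idx) {
    ex <- explain_instance(gb, z$train_X[i, , drop = FALSE], z$train_X)
    attr_sum <- attr_sum + ex$attributions[["H1_rr"]]
  }
  expect_gt(attr_sum / length(idx), 0)
})

test_that("duplicated rows leave the global ranking unchanged", {
  d <- make_overlap_data(n = 120, sep = 2, seed = 10)
  gb <- learner_gbdt(n_trees = 20)$fit(d$X, d$y, seed = 11)
  g1 <- explain_global(gb, as.data.frame(d$X), max_rows = 500)
  g2 <- explain_global(gb, as.data.frame(d$X[rep(seq_len(nrow(d$X)), 2), ]),
                       max_rows = 500)
  expect_identical(g1$feature, g2$feature)
  expect_equal(g1$importance, g2$importance, tolerance = 1e-9)
})
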