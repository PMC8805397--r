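# The three base learners behind one interface: each constructor returns a
# list with `name`, `fit(X, y)` and `predict_proba(model, X)`. The random
# forest and gradient-boosted trees are built on the package's compiled CART
# regression-tree grower (probability forests via class-fraction leaves;
# boosting via logistic-loss gradient steps with Newton leaf values). This
# keeps the stack self-contained: no external learner packages are needed.

as_num_matrix <- function(X) {
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

#' Logistic-regression learner
#'
#' Plain `stats::glm` binomial fit with a sigmoid output.
#' @param maxit IRLS iteration cap.
#' @return a learner interface list (`name`, `fit`, `predict_proba`).
#' @export
learner_logistic <- function(maxit = 50) {
  list(
    name = "logistic_regression",
    fit = function(X, y, seed = 1L) {
      df <- as.data.frame(as_num_matrix(X))
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(), maxit = maxit))
    },
    predict_proba = function(model, X) {
      as.numeric(predict(model, newdata = as.data.frame(as_num_matrix(X)),
                         type = "response"))
    })
}

#' Random-forest learner
#'
#' Bagged probability trees: each tree is grown on a bootstrap sample with
#' per-node feature subsampling (`mtry`, default `sqrt(p)`) and variance
#' splitting on the 0/1 response; leaf values are class fractions and the
#' forest prediction is their average.
#'
#' @param n_trees number of trees (default 100).
#' @param max_depth per-tree depth cap.
#' @param min_node minimal node size.
#' @param mtry features tried per node; `NULL` for `floor(sqrt(p))`.
#' @return a learner interface list.
#' @export
learner_random_forest <- function(n_trees = 100L, max_depth = 12L,
                                  min_node = 5L, mtry = NULL) {
  list(
    name = "random_forest",
    fit = function(X, y, seed = 1L) {
      X <- as_num_matrix(X)
      n <- nrow(X); p <- ncol(X)
      mt <- mtry %||% max(1L, floor(sqrt(p)))
      trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
        rows <- sample.int(n, n, replace = TRUE) - 1L
        cart_build(X, as.numeric(y), rows, as.integer(max_depth),
                   as.integer(min_node), as.integer(mt),
                   sample.int(2147483646L, 1))
      }))
      structure(list(trees = trees, p = p, colnames = colnames(X)),
                class = "niv_rf")
    },
    predict_proba = function(model, X) {
      X <- as_num_matrix(X)
      acc <- rep(0, nrow(X))
      for (tr in model$trees) acc <- acc + cart_predict(tr, X)
      pmin(pmax(acc / length(model$trees), 0), 1)
    })
}

#' Gradient-boosted-trees learner
#'
#' Logistic-loss gradient boosting: shallow regression trees are fitted to
#' the current residual `y - p` and their leaf values replaced by a Newton
#' step `sum(residual) / sum(p (1 - p))` per leaf. Categorical inputs are
#' handled upstream via one-hot encoding with rare-category collapse.
#'
#' @param n_trees boosting rounds (default 100).
#' @param max_depth tree depth (default 3).
#' @param learning_rate shrinkage (default 0.1).
#' @param min_node minimal node size.
#' @param subsample row-subsampling fraction per round (default 1 = none).
#' @return a learner interface list.
#' @export
learner_gbdt <- function(n_trees = 100L, max_depth = 3L, learning_rate = 0.1,
                         min_node = 10L, subsample = 1.0) {
  list(
    name = "gbdt",
    fit = function(X, y, seed = 1L) {
      X <- as_num_matrix(X)
      n <- nrow(X)
      pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
      F0 <- qlogis(pbar)
      Fc <- rep(F0, n)
      trees <- vector("list", n_trees)
      with_seed(seed, {
        for (t in seq_len(n_trees)) {
          p <- plogis(Fc)
          r <- y - p
          rows <- if (subsample < 1)
            sort(sample.int(n, max(2L, floor(subsample * n)))) - 1L
          else seq_len(n) - 1L
          tr <- cart_build(X, r, rows, as.integer(max_depth),
                           as.integer(min_node), ncol(X),
                           sample.int(2147483646L, 1))
          # Newton leaf values on the rows that built the tree
          leaf <- cart_leaf_id(tr, X[rows + 1L, , drop = FALSE])
          num <- tapply(r[rows + 1L], leaf, sum)
          den <- tapply((p * (1 - p))[rows + 1L], leaf, sum)
          val <- tr$value * 0
          val[as.integer(names(num)) + 1L] <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
          tr$value <- val
          trees[[t]] <- tr
          Fc <- Fc + learning_rate * cart_predict(tr, X)
        }
      })
      structure(list(trees = trees, F0 = F0, shrink = learning_rate,
                     colnames = colnames(X)),
                class = "niv_gbdt")
    },
    predict_proba = function(model, X) {
      plogis(gbdt_margin(model, X))
    })
}

# raw log-odds of a fitted GBDT (SHAP for trees works in margin space)
gbdt_margin <- function(model, X) {
  X <- as_num_matrix(X)
  Fc <- rep(model$F0, nrow(X))
  for (tr in model$trees) Fc <- Fc + model$shrink * cart_predict(tr, X)
  Fc
}

#' The default base-learner trio
#'
#' Logistic regression, random forest and gradient-boosted trees, the
#' heterogeneous set combined by [fit_stack()].
#' @param rf_trees,gbdt_trees ensemble sizes.
#' @return named list of three learner interfaces.
#' @export
default_learners <- function(rf_trees = 100L, gbdt_trees = 100L) {
  list(logistic_regression = learner_logistic(),
       random_forest = learner_random_forest(n_trees = rf_trees),
       gbdt = learner_gbdt(n_trees = gbdt_trees))
}
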