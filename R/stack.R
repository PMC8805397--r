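# Stacking classifier: logistic regression, random forest and
# gradient-boosted trees as heterogeneous base learners; their out-of-fold
# predicted probabilities (stratified k-fold) form the 3-column training set
# of a logistic-regression meta learner. The base learners are then refit on
# the full training data for deployment.

#' Stacking configuration
#'
#' @param learners named list of base-learner interfaces (default
#'   [default_learners()]).
#' @param n_folds stratified folds for the out-of-fold meta features
#'   (default 5).
#' @param decision_threshold classification threshold on the meta
#'   probability, strictly inside (0,1).
#' @param seed integer RNG seed (fold assignment and learner fits).
#' @return an object of class `niv_stack_spec`.
#' @export
stack_spec <- function(learners = default_learners(), n_folds = 5L,
                       decision_threshold = 0.5, seed = 1L) {
  check_field(n_folds >= 2, "n_folds", "must be >= 2")
  check_field(decision_threshold > 0 && decision_threshold < 1,
              "decision_threshold", "must be strictly inside (0,1)")
  structure(list(learners = learners, n_folds = as.integer(n_folds),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "niv_stack_spec")
}

# stratified fold ids: both classes represented in every fold
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Fit the stacking classifier
#'
#' @param X numeric feature matrix / data.frame (preprocessed, typically
#'   oversampled training data).
#' @param y binary 0/1 labels.
#' @param spec a [stack_spec()].
#' @return an object of class `niv_stack`: refit base learners, the logistic
#'   meta learner trained on the out-of-fold probability matrix, the fold
#'   assignment and the meta-feature matrix.
#' @examples
#' \donttest{
#' X <- matrix(rnorm(600), 200, 3); y <- as.integer(X[, 1] + rnorm(200) > 0)
#' st <- fit_stack(X, y, stack_spec(n_folds = 3, seed = 1))
#' summary(predict_proba(st, X))
#' }
#' @export
fit_stack <- function(X, y, spec = stack_spec()) {
  X <- as_num_matrix(X)
  stopifnot(is_binary01(y), nrow(X) == length(y))
  if (min(table(y)) < spec$n_folds)
    stop("a class has fewer rows than n_folds; use fewer folds")
  seeds <- fanout_seeds(spec$seed, c("folds", paste0("fit_", names(spec$learners)),
                                     paste0("full_", names(spec$learners))))
  fold <- stratified_folds(y, spec$n_folds, seeds[["folds"]])
  L <- length(spec$learners)
  meta_X <- matrix(NA_real_, nrow(X), L,
                   dimnames = list(NULL, names(spec$learners)))
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("class absent from a training fold")
    for (l in seq_len(L)) {
      lr <- spec$learners[[l]]
      m <- lr$fit(X[tr, , drop = FALSE], y[tr],
                  seed = seeds[[paste0("fit_", names(spec$learners)[l])]] + f)
      meta_X[!tr, l] <- lr$predict_proba(m, X[!tr, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(meta_X)
  meta_df$.y <- y
  meta <- suppressWarnings(glm(.y ~ ., data = meta_df, family = binomial()))
  base <- lapply(seq_len(L), function(l)
    spec$learners[[l]]$fit(X, y,
      seed = seeds[[paste0("full_", names(spec$learners)[l])]]))
  names(base) <- names(spec$learners)
  structure(list(spec = spec, base = base, meta = meta, fold = fold,
                 meta_features = meta_X, colnames = colnames(X)),
            class = "niv_stack")
}

#' @export
print.niv_stack <- function(x, ...) {
  cat("<niv_stack>", length(x$base), "base learners (",
      paste(names(x$base), collapse = ", "), "),",
      x$spec$n_folds, "-fold out-of-fold meta features\n")
  invisible(x)
}

#' Predicted failure probabilities of a fitted stack
#'
#' Chains the refit base learners and the logistic meta learner.
#'
#' @param stack a fitted `niv_stack`.
#' @param X feature matrix with the training column layout.
#' @return numeric vector of probabilities in \[0,1\].
#' @export
predict_proba <- function(stack, X) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.niv_stack <- function(stack, X) {
  X <- as_num_matrix(X)
  if (!is.null(stack$colnames) && !is.null(colnames(X))) {
    miss <- setdiff(stack$colnames, colnames(X))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    X <- X[, stack$colnames, drop = FALSE]
  }
  bp <- base_probas(stack, X)
  as.numeric(predict(stack$meta, newdata = as.data.frame(bp), type = "response"))
}

# n x 3 matrix of base-learner probabilities
base_probas <- function(stack, X) {
  L <- length(stack$base)
  out <- matrix(NA_real_, nrow(X), L, dimnames = list(NULL, names(stack$base)))
  for (l in seq_len(L))
    out[, l] <- stack$spec$learners[[l]]$predict_proba(stack$base[[l]], X)
  out
}

#' Predicted labels of a fitted stack
#' @param object a fitted `niv_stack`.
#' @param X feature matrix.
#' @param threshold probability cutoff; label 1 iff probability >= threshold
#'   (default: the spec's `decision_threshold`).
#' @param ... unused.
#' @return integer 0/1 labels.
#' @export
predict.niv_stack <- function(object, X, threshold = NULL, ...) {
  threshold <- threshold %||% object$spec$decision_threshold
  as.integer(predict_proba(object, X) >= threshold)
}
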