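# Performance measures: confusion-matrix counts, accuracy, precision,
# recall, F1 and ROC AUC (Mann-Whitney form, ties counted half), plus
# benchmark harnesses comparing oversamplers and classifiers on a synthetic
# cohort. The positive class throughout is NIV failure (label 1).

#' Confusion matrix of binary predictions
#'
#' @param y_true,y_pred equal-length binary 0/1 vectors; 1 is the positive
#'   (failure) class.
#' @return an object of class `niv_confusion` with integer fields `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(is_binary01(y_true), is_binary01(y_pred))
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 TN = sum(y_true == 0 & y_pred == 0)),
            class = "niv_confusion")
}

#' @export
print.niv_confusion <- function(x, ...) {
  cat("      pred 1  pred 0\n")
  cat(sprintf("true 1 %5d  %5d\ntrue 0 %5d  %5d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

zero_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, returning 0")
    return(0)
  }
  num / den
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. A zero denominator yields 0 with a warning, so
#' degenerate folds never crash a benchmark.
#'
#' @param cm a [confusion()] object.
#' @return a number in \[0,1\].
#' @export
accuracy <- function(cm) {
  zero_div(cm$TP + cm$TN, cm$TP + cm$FP + cm$TN + cm$FN, "accuracy")
}

#' @rdname accuracy
#' @export
precision <- function(cm) zero_div(cm$TP, cm$TP + cm$FP, "precision")

#' @rdname accuracy
#' @export
recall <- function(cm) zero_div(cm$TP, cm$TP + cm$FN, "recall")

#' F1 score
#'
#' Harmonic mean `2 P R / (P + R)` of precision and recall; 0 when both are 0.
#' @param precision,recall numbers in \[0,1\].
#' @return the F1 score.
#' @examples
#' f1(0.814, 0.776)
#' @export
f1 <- function(precision, recall) {
  if (precision == 0 && recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC AUC (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half; computed from rank sums.
#'
#' @param y_true binary 0/1 labels, both classes present.
#' @param scores real-valued scores (higher = more positive).
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(is_binary01(y_true), length(y_true) == length(scores))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)   # mean ranks handle ties as 1/2
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' All five performance measures of a scored test set
#'
#' @param y_true binary labels.
#' @param scores predicted probabilities.
#' @param threshold classification cutoff (label 1 iff score >= threshold).
#' @param id configuration label for the row.
#' @return a one-row `data.frame`: `id`, `accuracy`, `auc`, `f1`,
#'   `precision`, `recall`.
#' @export
metrics_row <- function(y_true, scores, threshold = 0.5, id = "model") {
  cm <- confusion(y_true, as.integer(scores >= threshold))
  p <- suppressWarnings(precision(cm)); r <- suppressWarnings(recall(cm))
  data.frame(id = id, accuracy = accuracy(cm), auc = roc_auc(y_true, scores),
             f1 = f1(p, r), precision = p, recall = r,
             stringsAsFactors = FALSE)
}

#' Benchmark oversampling algorithms
#'
#' Mirrors the oversampler-comparison design: a fixed downstream classifier
#' (logistic regression by default) is trained on the training split after
#' each oversampler and scored on the held-out split.
#'
#' @param train_X,train_y,test_X,test_y preprocessed splits.
#' @param methods subset of `c("none","random","smote","borderline","svm",
#'   "modified")`.
#' @param classifier a learner interface (default [learner_logistic()]).
#' @param spec an [oversample_spec()].
#' @param seed integer seed for the classifier fits.
#' @return a `data.frame` with one metrics row per method.
#' @export
benchmark_oversamplers <- function(train_X, train_y, test_X, test_y,
                                   methods = c("none", "random", "smote",
                                               "borderline", "svm", "modified"),
                                   classifier = learner_logistic(),
                                   spec = oversample_spec(), seed = 1L) {
  stopifnot(length(methods) >= 1)
  do.call(rbind, lapply(methods, function(mth) {
    os <- oversample_baseline(train_X, train_y, mth, spec)
    m <- classifier$fit(os$X, os$y, seed = seed)
    metrics_row(test_y, classifier$predict_proba(m, test_X), id = mth)
  }))
}

#' Benchmark classifiers
#'
#' Mirrors the classifier-comparison design: every learner (and the full
#' stack) is trained on the same oversampled training split and scored on
#' the held-out split.
#'
#' @param train_X,train_y,test_X,test_y preprocessed splits (training
#'   already oversampled by the caller, matching the pipeline order).
#' @param learners named list of learner interfaces.
#' @param include_stack also fit and score the stacking model.
#' @param stackspec a [stack_spec()] used when `include_stack = TRUE`.
#' @param seed integer seed.
#' @return a `data.frame` with one metrics row per configuration.
#' @export
benchmark_classifiers <- function(train_X, train_y, test_X, test_y,
                                  learners = default_learners(),
                                  include_stack = TRUE,
                                  stackspec = NULL, seed = 1L) {
  stopifnot(length(learners) >= 1)
  rows <- lapply(names(learners), function(nm) {
    m <- learners[[nm]]$fit(train_X, train_y, seed = seed)
    metrics_row(test_y, learners[[nm]]$predict_proba(m, test_X), id = nm)
  })
  if (include_stack) {
    sp <- stackspec %||% stack_spec(learners = learners, seed = seed)
    st <- fit_stack(train_X, train_y, sp)
    rows <- c(rows, list(metrics_row(test_y, predict_proba(st, test_X),
                                     id = "stack")))
  }
  do.call(rbind, rows)
}
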