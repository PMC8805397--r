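# R interface to the compiled SMO solver: C-SVC with an RBF kernel. Used as
# the probe classifier that mines hard minority instances for the modified
# SMOTE oversampler, and as a baseline ("SVM SMOTE" support-vector seeding).

#' Fit an RBF-kernel support vector classifier
#'
#' C-SVC solved by sequential minimal optimization with maximal-violating-
#' pair working-set selection. `gamma` defaults to `1 / (p * var(X))`, the
#' usual "scale" heuristic.
#'
#' @param X numeric matrix (rows standardized upstream).
#' @param y binary 0/1 labels.
#' @param C box constraint (default 1).
#' @param gamma RBF kernel width; `NULL` for the scale heuristic.
#' @param eps SMO stopping tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `niv_svm`.
#' @export
svm_fit <- function(X, y, C = 1, gamma = NULL, eps = 1e-3, max_iter = 20000L) {
  X <- as.matrix(X)
  stopifnot(is_binary01(y), nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("both classes required")
  if (is.null(gamma)) {
    vx <- mean(apply(X, 2, var))
    gamma <- if (vx > 0) 1 / (ncol(X) * vx) else 1
  }
  ys <- ifelse(y == 1, 1, -1)
  fit <- svm_smo(X, ys, C, gamma, eps, as.integer(max_iter))
  structure(list(SV = X[fit$sv_index, , drop = FALSE], coef = fit$coef,
                 rho = fit$rho, gamma = gamma, C = C,
                 sv_index = fit$sv_index, iterations = fit$iterations),
            class = "niv_svm")
}

#' Decision values and labels of a fitted SVM
#' @param object a `niv_svm`.
#' @param X numeric matrix with the training column layout.
#' @param type `"decision"` for signed margins, `"class"` for 0/1 labels.
#' @param ... unused.
#' @return numeric decision values or 0/1 labels.
#' @export
predict.niv_svm <- function(object, X, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dec <- svm_decision(object$SV, object$coef, object$rho, object$gamma,
                      as.matrix(X))
  if (type == "decision") dec else as.integer(dec > 0)
}
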