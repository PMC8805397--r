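# Additive (SHAP-style) explanations.
#
# Three explainers, chosen by model class:
#  * tree ensembles (random forest, GBDT): the polynomial-time
#    path-dependent tree explainer -- expectations are taken under the
#    tree's own training cover distribution, attributions are exact and sum
#    to prediction - base value in the model's margin space (probability for
#    the forest, log-odds for the GBDT);
#  * logistic regression: the closed-form linear explainer in link space,
#    phi_j = beta_j (x_j - mean(reference_j));
#  * the stacking model: a seeded permutation-sampling explainer whose
#    telescoping construction makes attributions sum exactly to
#    f(x) - mean f(reference) even at small sample sizes.

# ---- path-dependent tree explainer over the package's flat tree arrays ----

path_extend <- function(pth, pz, po, pf) {
  l <- length(pth$pw) + 1L
  pth$fidx[l] <- pf; pth$zf[l] <- pz; pth$of[l] <- po
  pth$pw[l] <- if (l == 1L) 1 else 0
  if (l > 1L) for (i in (l - 1L):1L) {
    pth$pw[i + 1L] <- pth$pw[i + 1L] + po * pth$pw[i] * i / l
    pth$pw[i] <- pz * pth$pw[i] * (l - i) / l
  }
  pth
}

path_unwound_sum <- function(pth, pos) {
  l <- length(pth$pw)
  ofi <- pth$of[pos]; zfi <- pth$zf[pos]
  nxt <- pth$pw[l]; total <- 0
  for (i in (l - 1L):1L) {
    if (ofi != 0) {
      tmp <- nxt * l / (i * ofi)
      total <- total + tmp
      nxt <- pth$pw[i] - tmp * zfi * (l - i) / l
    } else if (zfi != 0) {
      total <- total + pth$pw[i] * l / (zfi * (l - i))
    }
  }
  total
}

path_unwind <- function(pth, pos) {
  l <- length(pth$pw)
  ofi <- pth$of[pos]; zfi <- pth$zf[pos]
  nxt <- pth$pw[l]
  for (i in (l - 1L):1L) {
    if (ofi != 0) {
      tmp <- pth$pw[i]
      pth$pw[i] <- nxt * l / (i * ofi)
      nxt <- tmp - pth$pw[i] * zfi * (l - i) / l
    } else {
      pth$pw[i] <- pth$pw[i] * l / (zfi * (l - i))
    }
  }
  if (pos <= l - 1L) for (i in pos:(l - 1L)) {
    pth$fidx[i] <- pth$fidx[i + 1L]
    pth$zf[i] <- pth$zf[i + 1L]
    pth$of[i] <- pth$of[i + 1L]
  }
  pth$fidx <- pth$fidx[-l]; pth$zf <- pth$zf[-l]
  pth$of <- pth$of[-l]; pth$pw <- pth$pw[-l]
  pth
}

# SHAP values of one CART tree for one instance x (0-based features in tree)
tree_shap_one <- function(tree, x) {
  phi <- numeric(length(x))
  rec <- function(node, pth, pz, po, pf) {
    pth <- path_extend(pth, pz, po, pf)
    l <- length(pth$pw)
    f <- tree$feature[node]
    if (f < 0) {
      if (l >= 2L) for (i in 2:l)
        phi[pth$fidx[i] + 1L] <<- phi[pth$fidx[i] + 1L] +
          path_unwound_sum(pth, i) * (pth$of[i] - pth$zf[i]) * tree$value[node]
      return(invisible())
    }
    left <- tree$left[node] + 1L; right <- tree$right[node] + 1L
    hot <- if (x[f + 1L] <= tree$threshold[node]) left else right
    cold <- if (hot == left) right else left
    iz <- 1; io <- 1
    k <- which(pth$fidx == f)
    if (length(k)) {
      iz <- pth$zf[k[1]]; io <- pth$of[k[1]]
      pth <- path_unwind(pth, k[1])
    }
    rec(hot, pth, iz * tree$cover[hot] / tree$cover[node], io, f)
    rec(cold, pth, iz * tree$cover[cold] / tree$cover[node], 0, f)
  }
  rec(1L, list(fidx = integer(0), zf = numeric(0), of = numeric(0),
               pw = numeric(0)), 1, 1, -1L)
  phi
}

# cover-weighted mean prediction of one tree (its base value)
tree_base_value <- function(tree) {
  leaves <- tree$feature < 0
  sum(tree$value[leaves] * tree$cover[leaves]) / tree$cover[1]
}

#' Explain a single prediction additively
#'
#' Returns per-feature attributions satisfying
#' `base_value + sum(attributions) = prediction` (to 1e-6 for the exact tree
#' and linear explainers; exactly, by construction, for the sampling
#' explainer used on the stack). Tree models are explained in margin space
#' (class fraction for the forest, log-odds for the GBDT), logistic
#' regression in link space, and the stack in probability space.
#'
#' @param model a fitted base learner (`niv_rf`, `niv_gbdt`, a `glm`) or a
#'   fitted `niv_stack`.
#' @param x a single feature row (named numeric vector or 1-row matrix /
#'   data.frame) in the model's training column layout.
#' @param reference background feature matrix (typically the training
#'   split); defines the expectation `E[f(X)]` for the linear and sampling
#'   explainers. The tree explainer uses the trees' own cover distribution.
#' @param nsim permutations for the sampling explainer (stack only).
#' @param n_background background rows subsampled for the sampling explainer.
#' @param seed integer seed for the sampling explainer.
#' @param instance_id optional identifier carried into the result.
#' @return an object of class `niv_explanation`: `base_value`,
#'   `attributions` (named), `prediction`, `output_space`, `instance_id`.
#' @examples
#' \donttest{
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- as.integer(X[, 1] > 0)
#' lr <- learner_logistic()
#' m <- lr$fit(X, y)
#' ex <- explain_instance(m, X[1, ], X)
#' ex$base_value + sum(ex$attributions) - ex$prediction  # ~ 0
#' }
#' @export
explain_instance <- function(model, x, reference, nsim = 20L,
                             n_background = 25L, seed = 1L,
                             instance_id = NULL) {
  UseMethod("explain_instance")
}

as_feature_row <- function(x, cols) {
  if (is.data.frame(x) || is.matrix(x)) {
    stopifnot(nrow(x) == 1)
    x <- stats::setNames(as.numeric(as_num_matrix(x)[1, ]), colnames(x))
  }
  if (!is.null(cols)) {
    miss <- setdiff(cols, names(x))
    if (length(miss)) stop("instance lacks columns: ", paste(miss, collapse = ", "))
    x <- x[cols]
  }
  x
}

new_explanation <- function(base, phi, pred, space, id) {
  structure(list(base_value = base, attributions = phi, prediction = pred,
                 output_space = space, instance_id = id),
            class = "niv_explanation")
}

#' @export
print.niv_explanation <- function(x, ...) {
  cat("<niv_explanation>", x$output_space, "space: base", signif(x$base_value, 4),
      "+ sum(phi)", signif(sum(x$attributions), 4), "= prediction",
      signif(x$prediction, 4), "\n")
  top <- head(x$attributions[order(-abs(x$attributions))], 5)
  for (nm in names(top)) cat(sprintf("  %-24s %+0.4f\n", nm, top[[nm]]))
  invisible(x)
}

#' @export
explain_instance.niv_rf <- function(model, x, reference, nsim = 20L,
                                    n_background = 25L, seed = 1L,
                                    instance_id = NULL) {
  x <- as_feature_row(x, model$colnames)
  phi <- numeric(length(x)); base <- 0
  for (tr in model$trees) {
    phi <- phi + tree_shap_one(tr, x)
    base <- base + tree_base_value(tr)
  }
  k <- length(model$trees)
  pred <- (base + sum(phi)) / k
  new_explanation(base / k, stats::setNames(phi / k, names(x)), pred,
                  "probability", instance_id)
}

#' @export
explain_instance.niv_gbdt <- function(model, x, reference, nsim = 20L,
                                      n_background = 25L, seed = 1L,
                                      instance_id = NULL) {
  x <- as_feature_row(x, model$colnames)
  phi <- numeric(length(x)); base <- model$F0
  for (tr in model$trees) {
    phi <- phi + model$shrink * tree_shap_one(tr, x)
    base <- base + model$shrink * tree_base_value(tr)
  }
  new_explanation(base, stats::setNames(phi, names(x)), base + sum(phi),
                  "margin", instance_id)
}

#' @export
explain_instance.glm <- function(model, x, reference, nsim = 20L,
                                 n_background = 25L, seed = 1L,
                                 instance_id = NULL) {
  cf <- stats::coef(model)
  cf[is.na(cf)] <- 0
  feats <- setdiff(names(cf), "(Intercept)")
  x <- as_feature_row(x, feats)
  ref <- as_num_matrix(as.data.frame(reference)[feats])
  mu <- colMeans(ref)
  phi <- cf[feats] * (x - mu)
  base <- cf[["(Intercept)"]] + sum(cf[feats] * mu)
  new_explanation(base, stats::setNames(as.numeric(phi), feats),
                  base + sum(phi), "margin", instance_id)
}

#' @export
explain_instance.niv_stack <- function(model, x, reference, nsim = 20L,
                                       n_background = 25L, seed = 1L,
                                       instance_id = NULL) {
  x <- as_feature_row(x, model$colnames)
  ref <- as_num_matrix(as.data.frame(reference)[names(x)])
  p <- length(x)
  with_seed(seed, {
    if (nrow(ref) > n_background)
      ref <- ref[sample.int(nrow(ref), n_background), , drop = FALSE]
    nb <- nrow(ref)
    phi <- numeric(p)
    # one evaluation block per permutation: rows 1..(p+1) walk from the
    # background row to x, flipping one feature at a time
    for (s in seq_len(nsim)) {
      perm <- sample.int(p)
      big <- matrix(NA_real_, nb * (p + 1), p, dimnames = list(NULL, names(x)))
      for (b in seq_len(nb)) {
        block <- matrix(rep(ref[b, ], p + 1), p + 1, p, byrow = TRUE)
        for (step in seq_len(p))
          block[(step + 1):(p + 1), perm[step]] <- x[perm[step]]
        big[((b - 1) * (p + 1) + 1):(b * (p + 1)), ] <- block
      }
      f <- predict_proba(model, big)
      fm <- matrix(f, p + 1, nb)             # steps x backgrounds
      marg <- rowMeans(fm[-1, , drop = FALSE] - fm[-(p + 1), , drop = FALSE])
      phi[perm] <- phi[perm] + marg
    }
    phi <- phi / nsim
    base <- mean(predict_proba(model, ref))
    new_explanation(base, stats::setNames(phi, names(x)), base + sum(phi),
                    "probability", instance_id)
  })
}

#' Global feature importance
#'
#' Mean absolute attribution per feature over a dataset, ranked descending.
#'
#' @param model a fitted learner or stack accepted by [explain_instance()].
#' @param X feature matrix of instances to explain.
#' @param reference background matrix (defaults to `X`).
#' @param max_rows cap on explained rows (subsampled deterministically).
#' @param ... passed to [explain_instance()].
#' @return an object of class `niv_global_importance`: a `data.frame` with
#'   `feature` and `importance`, sorted by decreasing importance.
#' @export
explain_global <- function(model, X, reference = X, max_rows = 100L, ...) {
  X <- as.data.frame(X)
  if (!nrow(X)) stop("X is empty")
  if (nrow(X) > max_rows)
    X <- X[with_seed(1L, sample.int(nrow(X), max_rows)), , drop = FALSE]
  acc <- NULL
  for (i in seq_len(nrow(X))) {
    ex <- explain_instance(model, X[i, , drop = FALSE], reference, ...)
    a <- abs(ex$attributions)
    acc <- if (is.null(acc)) a else acc + a
  }
  imp <- acc / nrow(X)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("niv_global_importance", "data.frame")
  out
}
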