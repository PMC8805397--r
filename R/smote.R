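# Modified SMOTE oversampler.
#
# Pipeline: (1) an RBF-SVM probe is fitted on the full training partition
# and the minority rows it misclassifies in-sample form the hard-instance
# set; (2) hard instances none of whose m nearest neighbours (any class) is
# minority are removed as isolated; (3) the retained hard instances are
# k-means clustered into N groups; (4) synthetic minority rows are drawn as
# convex combinations x_new = c_j + u * (x_i - c_j) of a cluster centroid
# c_j and a member x_i, with u ~ Uniform(0,1), until the requested
# minority/majority ratio is reached. Compared with classic SMOTE this
# concentrates synthesis on the hard (boundary) region while refusing to
# amplify isolated noise points.

#' Oversampler configuration
#'
#' @param m isolation neighbourhood size: a hard instance is isolated when
#'   none of its `m` nearest neighbours (all classes) is minority (default 5).
#' @param n_clusters number of k-means clusters for the hard set, or
#'   `"auto"` for `max(1, round(sqrt(#retained)))`.
#' @param target_ratio desired minority/majority ratio after oversampling,
#'   in (0, 1] (default 1: full balance).
#' @param svm_C,svm_gamma probe-SVM regularization and kernel width
#'   (`NULL` gamma = scale heuristic).
#' @param seed integer RNG seed.
#' @return an object of class `niv_oversample_spec`.
#' @export
oversample_spec <- function(m = 5L, n_clusters = "auto", target_ratio = 1.0,
                            svm_C = 1, svm_gamma = NULL, seed = 1L) {
  check_field(m >= 1, "m", "must be >= 1")
  check_field(identical(n_clusters, "auto") ||
                (is.numeric(n_clusters) && n_clusters >= 1),
              "n_clusters", "must be a positive integer or \"auto\"")
  check_field(target_ratio > 0 && target_ratio <= 1, "target_ratio",
              "must be in (0, 1]")
  structure(list(m = as.integer(m), n_clusters = n_clusters,
                 target_ratio = target_ratio, svm_C = svm_C,
                 svm_gamma = svm_gamma, seed = as.integer(seed)),
            class = "niv_oversample_spec")
}

#' Mine hard minority instances with an SVM probe
#'
#' Fits the RBF-SVM probe on `(X, y)` and returns the minority rows whose
#' in-sample prediction is not the minority label.
#'
#' @param X standardized numeric feature matrix.
#' @param y binary 0/1 labels; 1 is the minority (failure) class.
#' @param spec an [oversample_spec()].
#' @return an object of class `niv_hard_set` with fields `indices` (hard
#'   minority row indices), `removed` (filled by [remove_isolated()]) and
#'   `minority` (all minority indices).
#' @export
find_hard_instances <- function(X, y, spec = oversample_spec()) {
  X <- as_num_matrix(X)
  stopifnot(is_binary01(y), nrow(X) == length(y))
  minority <- which(y == 1)
  if (length(minority) < 2) stop("need at least 2 minority instances")
  if (length(unique(y)) < 2) stop("both classes required")
  fit <- svm_fit(X, y, C = spec$svm_C, gamma = spec$svm_gamma)
  pred <- predict(fit, X, type = "class")
  structure(list(indices = minority[pred[minority] != 1],
                 removed = integer(0), minority = minority),
            class = "niv_hard_set")
}

#' Remove isolated instances from a hard set
#'
#' A hard instance is isolated when none of its `m` nearest neighbours
#' (Euclidean distance, among all rows of `X` excluding itself) belongs to
#' the minority class.
#'
#' @param hard a `niv_hard_set` from [find_hard_instances()].
#' @param X,y the matrix and labels the hard set was mined from.
#' @param m neighbourhood size.
#' @return the hard set with isolated indices moved to `removed`.
#' @export
remove_isolated <- function(hard, X, y, m = 5L) {
  stopifnot(inherits(hard, "niv_hard_set"), m >= 1)
  X <- as_num_matrix(X)
  iso <- vapply(hard$indices, function(i) {
    d2 <- colSums((t(X) - X[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(min(m, nrow(X) - 1))]
    !any(y[nb] == 1)
  }, TRUE)
  hard$removed <- hard$indices[iso]
  hard$indices <- hard$indices[!iso]
  hard
}

#' k-means clustering of the retained hard instances
#'
#' @param points numeric matrix of retained hard instances.
#' @param N number of clusters or `"auto"` (square-root rule); capped at the
#'   number of distinct points.
#' @param seed integer RNG seed.
#' @return list with `assignment` (cluster id per point) and `centers`
#'   (cluster-mean matrix).
#' @export
cluster_hard <- function(points, N = "auto", seed = 1L) {
  points <- as_num_matrix(points)
  if (nrow(points) < 1) stop("empty hard set: caller should fall back to classic SMOTE")
  if (identical(N, "auto")) N <- max(1L, round(sqrt(nrow(points))))
  N <- min(as.integer(N), nrow(unique(points)))
  if (N == 1 || nrow(points) == 1) {
    return(list(assignment = rep(1L, nrow(points)),
                centers = matrix(colMeans(points), 1,
                                 dimnames = list(NULL, colnames(points)))))
  }
  km <- with_seed(seed, kmeans(points, centers = N, nstart = 5, iter.max = 50))
  list(assignment = km$cluster, centers = km$centers)
}

#' Synthesize minority points from clustered hard instances
#'
#' Each synthetic row is `centre + u * (member - centre)` with
#' `u ~ Uniform(0, 1)`; the cluster is chosen with probability proportional
#' to its size and the member uniformly within it. Per-row provenance
#' (cluster id, seed-instance index, `u`) is recorded.
#'
#' @param clusters a [cluster_hard()] result.
#' @param points the clustered instance matrix (rows match `assignment`).
#' @param point_indices original row indices of `points` in the training
#'   matrix (for provenance).
#' @param n_needed number of rows to synthesize.
#' @param seed integer RNG seed.
#' @return an object of class `niv_synthetic_batch`: `X` (synthetic rows)
#'   and `provenance` (`data.frame` with `cluster`, `seed_index`, `u`).
#' @export
synthesize <- function(clusters, points, point_indices, n_needed, seed = 1L) {
  if (n_needed < 0) stop("n_needed must be non-negative")
  points <- as_num_matrix(points)
  p <- ncol(points)
  if (n_needed == 0) {
    return(structure(list(X = matrix(0, 0, p, dimnames = list(NULL, colnames(points))),
                          provenance = data.frame(cluster = integer(0),
                                                  seed_index = integer(0),
                                                  u = numeric(0))),
                     class = "niv_synthetic_batch"))
  }
  sizes <- tabulate(clusters$assignment, nbins = nrow(clusters$centers))
  with_seed(seed, {
    cl <- sample.int(length(sizes), n_needed, replace = TRUE, prob = sizes)
    u <- runif(n_needed)
    member <- vapply(cl, function(j) {
      cand <- which(clusters$assignment == j)
      cand[sample.int(length(cand), 1)]
    }, 0L)
    Xs <- clusters$centers[cl, , drop = FALSE] +
      u * (points[member, , drop = FALSE] - clusters$centers[cl, , drop = FALSE])
    colnames(Xs) <- colnames(points)
    structure(list(X = Xs,
                   provenance = data.frame(cluster = cl,
                                           seed_index = point_indices[member],
                                           u = u,
                                           centroid = I(lapply(cl, function(j)
                                             unname(clusters$centers[j, ]))))),
              class = "niv_synthetic_batch")
  })
}

n_to_synthesize <- function(y, target_ratio) {
  n_min <- sum(y == 1); n_maj <- sum(y == 0)
  max(0L, as.integer(round(target_ratio * n_maj)) - n_min)
}

#' Modified SMOTE oversampling
#'
#' Runs the full hard-instance pipeline (SVM probe, isolation removal,
#' k-means, centroid-member interpolation) and appends synthetic minority
#' rows until `minority/majority = target_ratio`. Original rows are returned
#' unchanged, first, in their input order. When the hard set is empty or
#' entirely isolated the sampler falls back to classic SMOTE over all
#' minority rows, with a warning.
#'
#' @param X standardized numeric feature matrix.
#' @param y binary 0/1 labels (1 = minority).
#' @param spec an [oversample_spec()].
#' @return list with `X`, `y` (augmented data), `report` (hard set, removed
#'   set, per-row synthesis provenance, method used).
#' @examples
#' \donttest{
#' d <- generate_cohort(cohort_spec(300, failure_rate = 0.15, seed = 1))
#' X <- scale(as.matrix(d[measurement_columns(d)]))
#' X[is.na(X)] <- 0
#' os <- oversample(X, d$niv_failure, oversample_spec(seed = 2))
#' table(os$y)
#' }
#' @export
oversample <- function(X, y, spec = oversample_spec()) {
  X <- as_num_matrix(X)
  stopifnot(is_binary01(y))
  if (length(unique(y)) < 2) stop("both classes required")
  need <- n_to_synthesize(y, spec$target_ratio)
  if (need == 0) {
    return(list(X = X, y = y,
                report = list(method = "none", n_synthetic = 0L,
                              hard = integer(0), removed = integer(0),
                              provenance = NULL)))
  }
  seeds <- fanout_seeds(spec$seed, c("probe", "cluster", "synth", "fallback"))
  hard <- find_hard_instances(X, y, spec)
  hard <- remove_isolated(hard, X, y, spec$m)

  if (length(hard$indices) == 0) {
    warning("hard-instance set empty after isolation removal; ",
            "falling back to classic SMOTE")
    Xs <- smote_interpolate(X, which(y == 1), need, k = 5L,
                            seed = seeds[["fallback"]])
    batch <- NULL; method <- "fallback_smote"
  } else {
    pts <- X[hard$indices, , drop = FALSE]
    clusters <- cluster_hard(pts, spec$n_clusters, seed = seeds[["cluster"]])
    batch <- synthesize(clusters, pts, hard$indices, need,
                        seed = seeds[["synth"]])
    Xs <- batch$X; method <- "modified_smote"
  }
  list(X = rbind(X, Xs), y = c(y, rep(1L, nrow(Xs))),
       report = list(method = method, n_synthetic = nrow(Xs),
                     hard = hard$indices, removed = hard$removed,
                     provenance = if (!is.null(batch)) batch$provenance))
}

# classic SMOTE interpolation used by the fallback and the baseline:
# new point = x + u * (neighbour - x) among the k nearest minority rows
smote_interpolate <- function(X, seed_rows, n_needed, k = 5L, seed = 1L) {
  if (n_needed == 0) return(X[integer(0), , drop = FALSE])
  M <- X[seed_rows, , drop = FALSE]
  nm <- nrow(M)
  if (nm == 1) return(M[rep(1, n_needed), , drop = FALSE])
  D2 <- as.matrix(stats::dist(M))^2
  diag(D2) <- Inf
  kk <- min(k, nm - 1)
  ord <- apply(D2, 1, function(d) order(d)[seq_len(kk)])
  nn <- if (kk == 1) matrix(ord, ncol = 1) else t(ord)
  with_seed(seed, {
    i <- sample.int(nm, n_needed, replace = TRUE)
    j <- nn[cbind(i, sample.int(kk, n_needed, replace = TRUE))]
    u <- runif(n_needed)
    M[i, , drop = FALSE] + u * (M[j, , drop = FALSE] - M[i, , drop = FALSE])
  })
}

#' Baseline oversamplers
#'
#' The comparison set behind the same signature as [oversample()]: random
#' duplication, classic SMOTE, Borderline-SMOTE (synthesis restricted to
#' "danger" minority rows: more than half but not all of their k minority-
#' search neighbours are majority) and SVM-SMOTE (synthesis seeded at the
#' minority support vectors of an RBF-SVM).
#'
#' @param X,y as in [oversample()].
#' @param method one of `"random"`, `"smote"`, `"borderline"`, `"svm"`,
#'   `"modified"`, `"none"`.
#' @param spec an [oversample_spec()] (`target_ratio`, `seed`, SVM settings).
#' @param k neighbourhood size for the SMOTE-family samplers.
#' @return list with `X`, `y`, `report$method`.
#' @export
oversample_baseline <- function(X, y, method = c("random", "smote",
                                                 "borderline", "svm",
                                                 "modified", "none"),
                                spec = oversample_spec(), k = 5L) {
  method <- match.arg(method)
  if (method == "modified") return(oversample(X, y, spec))
  X <- as_num_matrix(X)
  need <- n_to_synthesize(y, spec$target_ratio)
  if (method == "none" || need == 0)
    return(list(X = X, y = y, report = list(method = method, n_synthetic = 0L)))
  mino <- which(y == 1)
  Xs <- switch(method,
    random = with_seed(spec$seed,
      X[mino[sample.int(length(mino), need, replace = TRUE)], , drop = FALSE]),
    smote = smote_interpolate(X, mino, need, k, spec$seed),
    borderline = {
      danger <- borderline_danger(X, y, mino, k)
      if (!length(danger)) danger <- mino   # degenerate: no border region
      smote_interpolate(X, danger, need, k, spec$seed)
    },
    svm = {
      fit <- svm_fit(X, y, C = spec$svm_C, gamma = spec$svm_gamma)
      seeds_sv <- intersect(fit$sv_index, mino)
      if (length(seeds_sv) < 2) seeds_sv <- mino
      smote_interpolate(X, seeds_sv, need, k, spec$seed)
    })
  list(X = rbind(X, Xs), y = c(y, rep(1L, nrow(Xs))),
       report = list(method = method, n_synthetic = nrow(Xs)))
}

# minority rows in the Borderline-SMOTE "danger" zone
borderline_danger <- function(X, y, mino, k = 5L) {
  mino[vapply(mino, function(i) {
    d2 <- colSums((t(X) - X[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(min(k, nrow(X) - 1))]
    nmaj <- sum(y[nb] == 0)
    nmaj > length(nb) / 2 && nmaj < length(nb)
  }, TRUE)]
}
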