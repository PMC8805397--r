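test_that("hard instances are misclassified minority rows only", {
  # separable: the probe makes no error, so the hard set is empty
  d <- make_separable_data(seed = 1)
  hs <- find_hard_instances(d$X, d$y)
  expect_length(hs$indices, 0)

  # a minority point duplicated deep inside the majority blob is hard
  set.seed(2)
  Xmaj <- matrix(rnorm(200 * 3), 200, 3)
  Xmin <- matrix(rnorm(30 * 3, mean = 5), 30, 3)
  X <- rbind(Xmaj, Xmin, Xmaj[1, , drop = FALSE])
  y <- c(rep(0, 200), rep(1, 31))
  hs2 <- find_hard_instances(X, y)
  expect_true(231 %in% hs2$indices)
  expect_true(all(hs2$indices %in% which(y == 1)))   # subset of minority
  expect_error(find_hard_instances(X, rep(1, nrow(X))), "classes")
})

test_that("remove_isolated drops points with no minority neighbours", {
  set.seed(3)
  # minority clump farther from the isolated point than the majority blob,
  # so the isolated point's nearest neighbours are all majority
  X <- rbind(matrix(rnorm(100 * 2), 100, 2),          # majority at origin
             matrix(rnorm(10 * 2, mean = -5), 10, 2), # minority clump
             c(50, 50))                               # isolated minority
  y <- c(rep(0, 100), rep(1, 11))
  hard <- structure(list(indices = c(101L, 111L), removed = integer(0),
                         minority = which(y == 1)), class = "niv_hard_set")
  out <- remove_isolated(hard, X, y, m = 5)
  expect_identical(out$removed, 111L)
  expect_identical(out$indices, 101L)

  # brute-force oracle: 5-NN of row 111 contains no minority
  d2 <- colSums((t(X) - X[111, ])^2); d2[111] <- Inf
  expect_false(any(y[order(d2)[1:5]] == 1))

  # a hard instance with a minority twin at distance zero is retained
  X2 <- rbind(X[1:111, ], X[111, , drop = FALSE])
  y2 <- c(y, 1)
  hard2 <- structure(list(indices = 111L, removed = integer(0),
                          minority = which(y2 == 1)), class = "niv_hard_set")
  expect_identical(remove_isolated(hard2, X2, y2, m = 5)$indices, 111L)

  # m >= n-1: nothing is isolated when any other minority point exists
  out3 <- remove_isolated(hard2, X2, y2, m = nrow(X2) - 1)
  expect_length(out3$removed, 0)
})

test_that("cluster_hard behaves like k-means on the hard set", {
  set.seed(4)
  blob1 <- matrix(rnorm(20 * 2), 20, 2)
  blob2 <- matrix(rnorm(25 * 2, mean = 10), 25, 2)
  pts <- rbind(blob1, blob2)

  one <- cluster_hard(pts, N = 1)
  expect_equal(as.numeric(one$centers), colMeans(pts))

  two <- cluster_hard(pts, N = 2, seed = 9)
  truth <- rep(1:2, c(20, 25))
  agree <- max(mean(two$assignment == truth), mean(two$assignment == 3 - truth))
  expect_equal(agree, 1)
  # centroid = mean of its members (k-means fixed point)
  for (j in 1:2)
    expect_lt(max(abs(two$centers[j, ] - colMeans(pts[two$assignment == j, ]))),
              1e-9)
  # "auto" uses the square-root rule, capped by distinct points
  expect_equal(nrow(cluster_hard(pts, "auto", 1)$centers),
               round(sqrt(45)))
  expect_error(cluster_hard(pts[0, ]), "empty")
})

test_that("synthesize emits convex centroid-member combinations", {
  set.seed(5)
  pts <- matrix(rnorm(12 * 3), 12, 3)
  cl <- cluster_hard(pts, N = 3, seed = 1)
  batch <- synthesize(cl, pts, seq_len(12), n_needed = 40, seed = 2)
  expect_equal(nrow(batch$X), 40)
  for (r in seq_len(40)) {
    ctr <- batch$provenance$centroid[[r]]
    seed_pt <- pts[batch$provenance$seed_index[r], ]
    u <- batch$provenance$u[r]
    expect_lt(max(abs(batch$X[r, ] - (ctr + u * (seed_pt - ctr)))), 1e-9)
    expect_true(u >= 0 && u <= 1)
  }
  # degenerate single-point cluster: centroid = the point, synthesis = copies
  single <- list(assignment = 1L, centers = matrix(pts[1, ], 1))
  b2 <- synthesize(single, pts[1, , drop = FALSE], 1L, 5, seed = 3)
  expect_true(all(abs(sweep(b2$X, 2, pts[1, ])) < 1e-12))
  expect_equal(nrow(synthesize(cl, pts, 1:12, 0)$X), 0)
  expect_error(synthesize(cl, pts, 1:12, -1), "non-negative")
})

test_that("oversample reaches the target ratio and keeps originals first", {
  d <- make_overlap_data(n = 100, minority_frac = 0.1, sep = 1, seed = 6)
  n_min <- sum(d$y); n_maj <- sum(d$y == 0)
  os <- oversample(d$X, d$y, oversample_spec(seed = 3))
  expect_equal(sum(os$y == 1), n_maj)                 # balance reached
  expect_equal(os$X[seq_len(nrow(d$X)), ], unname(d$X), ignore_attr = TRUE)
  expect_equal(os$y[seq_len(nrow(d$X))], d$y)
  # counting example: 90 majority / 10 minority -> 80 synthetic rows
  expect_equal(os$report$n_synthetic, n_maj - n_min)
  # determinism: bit-identical output under the same seed
  os2 <- oversample(d$X, d$y, oversample_spec(seed = 3))
  expect_identical(os$X, os2$X)
  expect_identical(os$report$provenance, os2$report$provenance)

  # balanced input is a no-op
  bal <- make_overlap_data(n = 60, minority_frac = 0.5, seed = 7)
  bal$y <- rep_len(0:1, 60)
  osb <- oversample(bal$X, bal$y)
  expect_identical(osb$X, nivstack:::as_num_matrix(bal$X))
  expect_identical(osb$y, bal$y)
  expect_error(oversample(d$X, rep(0, length(d$y))), "classes")
})

test_that("isolated instances never seed synthesis", {
  tab <- generate_cohort(cohort_spec(n_patients = 250, failure_rate = 0.2,
                                     missing_rate = 0, outlier_rate = 0,
                                     seed = 8))
  tab <- plant_isolated_minority(tab, 3, separation = 12, seed = 9)
  Z <- scale(as.matrix(tab[measurement_columns(tab)]))
  os <- oversample(Z, tab$niv_failure, oversample_spec(seed = 10))
  planted <- which(grepl("^ISO", tab$patient_id))
  # planted points are either never mined as hard (the probe memorizes
  # them in-sample) or removed as isolated -- never retained for synthesis
  expect_length(intersect(os$report$hard, planted), 0)
  if (!is.null(os$report$provenance))
    expect_length(intersect(os$report$provenance$seed_index, planted), 0)
})

test_that("separable data falls back to classic SMOTE with a warning", {
  d <- make_separable_data(n = 100, seed = 11)
  # unbalance it: drop most minority rows
  keep <- c(which(d$y == 0), which(d$y == 1)[1:10])
  X <- d$X[keep, ]; y <- d$y[keep]
  expect_warning(os <- oversample(X, y, oversample_spec(seed = 12)),
                 "falling back")
  expect_equal(sum(os$y == 1), sum(os$y == 0))
  expect_equal(os$report$method, "fallback_smote")
  # fallback synthesis stays inside the minority convex hull (coordinate-wise)
  syn <- os$X[-seq_along(y), , drop = FALSE]
  for (j in seq_len(ncol(X))) {
    expect_gte(min(syn[, j]), min(X[y == 1, j]) - 1e-9)
    expect_lte(max(syn[, j]), max(X[y == 1, j]) + 1e-9)
  }
})

test_that("baseline oversamplers share the signature and hit the ratio", {
  d <- make_overlap_data(n = 150, minority_frac = 0.15, seed = 13)
  for (mth in c("random", "smote", "borderline", "svm")) {
    os <- oversample_baseline(d$X, d$y, mth, oversample_spec(seed = 14))
    expect_equal(sum(os$y == 1), sum(os$y == 0))
    expect_equal(os$report$method, mth)
  }
  non <- oversample_baseline(d$X, d$y, "none")
  expect_equal(length(non$y), length(d$y))
})
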