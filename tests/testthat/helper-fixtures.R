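# Shared in-code fixtures.

# standardized measurement-column matrices for a train/test cohort split;
# the minimal feature representation used by the oversampling and stacking
# property tests (full feature engineering is exercised separately)
std_split <- function(tab, fraction = 0.8, seed = 1L) {
  sp <- split_train_test(tab, fraction, seed)
  tr <- as.matrix(sp$train[measurement_columns(tab)])
  te <- as.matrix(sp$test[measurement_columns(tab)])
  mu <- colMeans(tr, na.rm = TRUE)
  s <- apply(tr, 2, sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  z <- function(M) {
    Z <- sweep(sweep(M, 2, mu), 2, s, "/")
    Z[is.na(Z)] <- 0
    Z
  }
  list(train_X = z(tr), train_y = sp$train$niv_failure,
       test_X = z(te), test_y = sp$test$niv_failure)
}

# two overlapping Gaussian blobs with an imbalanced minority
make_overlap_data <- function(n = 300, p = 4, minority_frac = 0.2,
                              sep = 1.5, seed = 1L) {
  set.seed(seed)
  y <- as.integer(runif(n) < minority_frac)
  X <- matrix(rnorm(n * p), n, p) + sep * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# linearly separable data (margin >> noise)
make_separable_data <- function(n = 120, p = 3, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p, sd = 0.3), n, p) + 6 * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
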