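mk_pairs <- function(base) data.frame(h0 = paste0("H0_", base),
                                      h1 = paste0("H1_", base), base = base,
                                      stringsAsFactors = FALSE)

test_that("temporal_mean_diff computes and inverts mean/differential", {
  m <- data.frame(H0_pao2 = c(72, 100), H1_pao2 = c(95, 100))
  out <- temporal_mean_diff(m, mk_pairs("pao2"))
  expect_equal(out$pao2_mean, c(83.5, 100))
  expect_equal(out$pao2_diff, c(23, 0))
  # algebraic inversion recovers (H1, H0) exactly
  expect_equal(out$pao2_mean + out$pao2_diff / 2, out$H1_pao2)
  expect_equal(out$pao2_mean - out$pao2_diff / 2, out$H0_pao2)
  expect_true(all(c("H0_pao2", "H1_pao2") %in% names(out)))  # originals kept
  expect_match(names(which(provenance(out)["pao2_mean"] == "manual")), "pao2")
  expect_error(temporal_mean_diff(m, mk_pairs("rr")), "H0_rr")
})

test_that("expert_features reproduces the clinician formulas", {
  m <- data.frame(age = 69, H0_pf = 178, H0_rr = 31, H0_hr = 134,
                  H0_fio2 = 0.42, H1_pf = 205, H1_rr = 27, H1_hr = 104,
                  H1_fio2 = 0.5)
  out <- expert_features(m)
  expect_equal(out$pf_per_rr_H0, 178 / 31)          # 5.7419...
  expect_equal(out$age_x_rr_H1, 1863)               # 69 * 27
  expect_equal(out$rr_x_hr_H0, 31 * 134)
  expect_equal(out$rr_x_hr_x_fio2_H1, 27 * 104 * 0.5)
  expect_equal(sum(provenance(out) == "expert"), 8)
  expect_equal(unname(attr(out, "units")["pf_per_rr_H0"]), "mmHg/breath/min")

  # all-zero FiO2 makes the triple product zero
  m2 <- m; m2$H0_fio2 <- 0
  expect_equal(expert_features(m2)$rr_x_hr_x_fio2_H0, 0)

  # RR = 0 sets the ratio missing (to be imputed downstream)
  m3 <- m; m3$H1_rr <- 0
  expect_warning(out3 <- expert_features(m3), "RR = 0")
  expect_true(is.na(out3$pf_per_rr_H1))
  expect_error(expert_features(m[-1]), "age")
})

test_that("feature_crosses multiplies listed pairs only", {
  m <- data.frame(a = c(1, 2), b = c(3, 4))
  out <- feature_crosses(m, list(c("a", "b")))
  expect_equal(out$a_x_b, c(3, 8))
  unchanged <- feature_crosses(m, list())
  expect_identical(names(unchanged), names(m))
  expect_identical(unchanged$a, m$a)
  out2 <- feature_crosses(m, list(c("a", "a")))
  expect_equal(out2$a_x_a, m$a^2)                  # self-cross = square
  expect_equal(unname(provenance(out)["a_x_b"]), "cross")
  expect_error(feature_crosses(m, list(c("a", "zz"))), "zz")
})

test_that("select_features applies variance then Pearson filters", {
  set.seed(3)
  y <- rep_len(c(0, 1), 100)
  m <- data.frame(const = rep(1, 100), noise = rnorm(100), label_copy = y)
  out <- select_features(m, y, variance_min = 1e-8, pearson_min = 0.01)
  rep_ <- attr(out, "selection_report")
  expect_true("const" %in% rep_$dropped_variance)
  expect_true("label_copy" %in% names(out))        # |r| = 1 always retained
  expect_error(select_features(data.frame(k = rep(0, 10)), rep_len(0:1, 10)),
               "dropped")
})

test_that("selection Pearson matches an independent formula and is monotone", {
  set.seed(9)
  y <- rbinom(200, 1, 0.4)
  m <- as.data.frame(matrix(rnorm(200 * 6), 200))
  m$V1 <- m$V1 + y
  # independent covariance/SD oracle
  for (j in seq_along(m)) {
    x <- m[[j]]
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
    expect_lt(abs(pearson_r(x, y) - oracle), 1e-9)
    expect_lt(abs(pearson_r(x, y) - cor(x, y)), 1e-9)
  }
  # monotone: raising either threshold never adds a feature
  base_keep <- names(select_features(m, y, 1e-8, 0.01))
  for (pm in c(0.05, 0.2, 0.5)) {
    kept <- tryCatch(names(select_features(m, y, 1e-8, pm)),
                     error = function(e) character(0))
    expect_true(all(kept %in% base_keep))
    base_keep <- kept
  }
})

test_that("every generated column carries exactly one known provenance tag", {
  tab <- generate_cohort(cohort_spec(n_patients = 150, missing_rate = 0,
                                     outlier_rate = 0, seed = 21))
  sp <- split_train_test(tab, 0.8, 1)
  fx <- build_features(sp$train, sp$test,
                       ae_spec = autoencoder_spec(epochs = 3), seed = 4)
  prov <- provenance(fx$train_X)
  expect_equal(length(prov), ncol(fx$train_X))
  expect_true(all(prov %in% c("raw", "manual", "expert", "cross", "deep")))
  expect_true(all(c("manual", "expert", "cross", "deep") %in% prov))
  expect_identical(names(prov), names(fx$train_X))
})
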