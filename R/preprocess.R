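# Leakage-safe preprocessing chain: 3-sigma outlier masking -> median
# imputation -> z-score standardization, plus one-hot encoding with
# rare-category collapse. All statistics are fitted on the training split
# only and replayed unchanged on test data.

#' Preprocessing configuration
#'
#' @param outlier_sigma multiplier of the standard deviation beyond which a
#'   value is masked as abnormal (default 3).
#' @param rare_category_threshold categories seen fewer than this many times
#'   in training are collapsed into `"Others"` (default 20).
#' @param split_fraction training fraction for [split_train_test()] (default 0.8).
#' @param stratify logical; stratify the split by outcome (default `FALSE`,
#'   i.e. a simple random split).
#' @param seed integer RNG seed.
#' @return an object of class `niv_preprocess_spec`.
#' @export
preprocess_spec <- function(outlier_sigma = 3, rare_category_threshold = 20L,
                            split_fraction = 0.8, stratify = FALSE, seed = 1L) {
  check_field(outlier_sigma > 0, "outlier_sigma", "must be > 0")
  check_field(split_fraction > 0 && split_fraction < 1, "split_fraction",
              "must be in (0,1)")
  check_field(rare_category_threshold >= 0, "rare_category_threshold",
              "must be >= 0")
  structure(list(outlier_sigma = outlier_sigma,
                 rare_category_threshold = as.integer(rare_category_threshold),
                 split_fraction = split_fraction, stratify = isTRUE(stratify),
                 seed = as.integer(seed)),
            class = "niv_preprocess_spec")
}

# population (divide-by-n) standard deviation; the convention used for both
# the z-score and the outlier bounds
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Flag abnormal values by the 3-sigma rule
#'
#' A value is abnormal when its distance from the column mean strictly
#' exceeds `sigma_mult` population standard deviations; flagged entries are
#' subsequently treated as missing.
#'
#' @param column numeric vector (may contain `NA`).
#' @param sigma_mult positive multiplier (default 3).
#' @return logical mask, `TRUE` where abnormal; `NA` entries are `FALSE`.
#' @examples
#' detect_outliers(c(rep(0, 100), 10))
#' @export
detect_outliers <- function(column, sigma_mult = 3) {
  stopifnot(sigma_mult > 0)
  obs <- column[is.finite(column)]
  if (length(obs) < 2) stop("need at least 2 finite values to detect outliers")
  m <- mean(obs); s <- pop_sd(column)
  mask <- abs(column - m) > sigma_mult * s
  mask[!is.finite(column)] <- FALSE
  mask
}

#' Fill missing entries with a (training) median
#'
#' @param column numeric vector with possible `NA`s.
#' @param median_value the median of the training-split observed values;
#'   must be finite.
#' @return the column with `NA`s replaced; observed entries unchanged.
#' @export
impute_median <- function(column, median_value) {
  if (!is.finite(median_value))
    stop("median_value is not finite (feature entirely missing in training?)")
  column[is.na(column)] <- median_value
  column
}

#' z-score standardization
#'
#' `x' = (x - center) / scale`, with training-split statistics.
#'
#' @param column numeric vector.
#' @param center training mean.
#' @param scale training population standard deviation, strictly positive.
#' @return standardized vector.
#' @export
zscore <- function(column, center, scale) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be a positive number")
  (column - center) / scale
}

#' One-hot encode a categorical column with rare-category collapse
#'
#' Categories observed fewer than `threshold` times in training are mapped to
#' `"Others"`, as are categories unseen at training time.
#'
#' @param column character/factor vector to encode.
#' @param levels_map optional character vector of retained categories (from a
#'   fitted preprocessor); when `NULL` it is computed from `column` itself.
#' @param threshold minimal training count for a category to keep its own
#'   indicator column.
#' @param prefix prefix for the output column names.
#' @return a `data.frame` of 0/1 indicator columns; each row sums to 1.
#' @export
onehot <- function(column, levels_map = NULL, threshold = 20L, prefix = "dx") {
  column <- as.character(column)
  if (is.null(levels_map)) {
    cnt <- table(column)
    levels_map <- sort(names(cnt)[cnt >= threshold])
  }
  levels_map <- setdiff(levels_map, "Others")
  mapped <- ifelse(column %in% levels_map, column, "Others")
  lv <- c(levels_map, "Others")
  block <- as.data.frame(lapply(lv, function(l) as.integer(mapped == l)))
  names(block) <- paste0(prefix, "_", gsub("[^A-Za-z0-9]", "_", lv))
  attr(block, "levels_map") <- levels_map
  block
}

#' Random train/test split
#'
#' @param table a `data.frame` with an outcome column `niv_failure` (only
#'   required when `stratify = TRUE`).
#' @param fraction training fraction in (0,1); the training size is
#'   `round(fraction * n)`.
#' @param seed integer RNG seed.
#' @param stratify stratify by `niv_failure`.
#' @return a list with elements `train` and `test` (disjoint partition).
#' @examples
#' sp <- split_train_test(data.frame(x = 1:10, niv_failure = rep(0:1, 5)), 0.5, 1)
#' nrow(sp$train)
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L, stratify = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  idx <- with_seed(seed, {
    if (isTRUE(stratify)) {
      pos <- which(table$niv_failure == 1); neg <- which(table$niv_failure == 0)
      c(sample(pos, round(fraction * length(pos))),
        sample(neg, round(fraction * n) - round(fraction * length(pos))))
    } else sample.int(n, round(fraction * n))
  })
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Fit the preprocessing chain on a training split
#'
#' Learns, per numeric feature: outlier bounds (mean +- `outlier_sigma` *
#' population SD), the median of the observed in-bound values, and the
#' z-score center/scale of the masked-and-imputed column. Zero-variance
#' features are dropped with a warning. Per categorical feature it learns the
#' retained-category map used for one-hot encoding.
#'
#' @param train training-split `data.frame`.
#' @param spec a [preprocess_spec()].
#' @param numeric_cols,categorical_cols column names to process; defaults to
#'   all numeric measurement-like columns / the `diagnosis` column.
#' @param passthrough columns copied through untouched (id, outcome, binary
#'   flags).
#' @return an object of class `niv_preprocessor`.
#' @seealso [apply_preprocessor()]
#' @export
fit_preprocessor <- function(train, spec = preprocess_spec(),
                             numeric_cols = NULL, categorical_cols = "diagnosis",
                             passthrough = NULL) {
  stopifnot(inherits(spec, "niv_preprocess_spec"))
  if (is.null(numeric_cols)) {
    num <- names(train)[vapply(train, is.numeric, TRUE)]
    flags <- names(train)[vapply(train, function(x)
      is.numeric(x) && all(x %in% c(0, 1, NA)), TRUE)]
    numeric_cols <- setdiff(num, c(flags, "niv_failure"))
  }
  categorical_cols <- intersect(categorical_cols, names(train))
  if (is.null(passthrough))
    passthrough <- setdiff(names(train), c(numeric_cols, categorical_cols))

  num_stats <- list(); dropped <- character(0)
  for (cn in numeric_cols) {
    x <- train[[cn]]
    if (all(is.na(x))) stop("feature entirely missing in training split: ", cn)
    mask <- detect_outliers(x, spec$outlier_sigma)
    x[mask] <- NA
    med <- median(x, na.rm = TRUE)
    x <- impute_median(x, med)
    s <- pop_sd(x)
    if (!is.finite(s) || s <= 0) {
      warning("dropping zero-variance feature: ", cn)
      dropped <- c(dropped, cn)
      next
    }
    num_stats[[cn]] <- list(mean = mean(train[[cn]], na.rm = TRUE),
                            sd = pop_sd(train[[cn]]),
                            median = med, center = mean(x), scale = s)
  }
  cat_maps <- lapply(categorical_cols, function(cn)
    attr(onehot(train[[cn]], threshold = spec$rare_category_threshold,
                prefix = cn), "levels_map"))
  names(cat_maps) <- categorical_cols

  structure(list(spec = spec, numeric = num_stats, dropped = dropped,
                 categorical = cat_maps, passthrough = passthrough),
            class = "niv_preprocessor")
}

#' Apply a fitted preprocessing chain
#'
#' Replays, with training statistics only: outlier masking -> median
#' imputation -> z-score scaling on numeric features, and one-hot encoding
#' (unseen categories to `"Others"`) on categorical features.
#'
#' @param fitted a [fit_preprocessor()] result.
#' @param table a cohort `data.frame` (train or test split).
#' @return a `data.frame`: passthrough columns, scaled numeric features, and
#'   indicator blocks.
#' @export
apply_preprocessor <- function(fitted, table) {
  stopifnot(inherits(fitted, "niv_preprocessor"))
  missing_cols <- setdiff(names(fitted$numeric), names(table))
  if (length(missing_cols))
    stop("table lacks fitted columns: ", paste(missing_cols, collapse = ", "))
  out <- table[intersect(fitted$passthrough, names(table))]
  for (cn in names(fitted$numeric)) {
    st <- fitted$numeric[[cn]]
    x <- table[[cn]]
    x[!is.na(x) & abs(x - st$mean) > fitted$spec$outlier_sigma * st$sd] <- NA
    x <- impute_median(x, st$median)
    out[[cn]] <- zscore(x, st$center, st$scale)
  }
  for (cn in names(fitted$categorical))
    out <- cbind(out, onehot(table[[cn]], levels_map = fitted$categorical[[cn]],
                             prefix = cn))
  out
}

#' Serialize a fitted preprocessor to JSON
#' @param fitted a `niv_preprocessor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_preprocessor <- function(fitted, path) {
  jsonlite::write_json(unclass(fitted), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
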