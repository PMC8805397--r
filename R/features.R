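# Feature engineering: temporal mean/differential features over the H0/H1
# pair, expert-formula features with pairwise crosses, and variance +
# Pearson feature selection. Every generated column carries a provenance
# tag in the matrix's "provenance" attribute: raw, manual, expert, cross or
# deep.

set_provenance <- function(df, cols, tag) {
  prov <- attr(df, "provenance") %||%
    stats::setNames(rep("raw", ncol(df)), names(df))
  prov[cols] <- tag
  prov <- prov[names(df)[names(df) %in% names(prov)]]
  # new columns default to raw
  add <- setdiff(names(df), names(prov))
  if (length(add)) prov <- c(prov, stats::setNames(rep("raw", length(add)), add))
  attr(df, "provenance") <- prov[names(df)]
  df
}

#' Column provenance tags of a feature matrix
#' @param matrix a feature `data.frame` produced by this package.
#' @return named character vector with one tag per column, from
#'   `raw`, `manual`, `expert`, `cross`, `deep`.
#' @export
provenance <- function(matrix) {
  attr(matrix, "provenance") %||%
    stats::setNames(rep("raw", ncol(matrix)), names(matrix))
}

#' Temporal mean and differential features
#'
#' For every H0/H1 pair adds `<base>_mean = (H0 + H1) / 2` and
#' `<base>_diff = H1 - H0`; the original columns are retained. The mapping
#' is invertible: `(mean + diff/2, mean - diff/2)` recovers `(H1, H0)`.
#'
#' @param matrix feature `data.frame` with imputed numeric paired columns.
#' @param pairs a [paired_feature_map()] `data.frame` (`h0`, `h1`, `base`).
#' @return the matrix with `2 * nrow(pairs)` added columns, tagged `manual`.
#' @export
temporal_mean_diff <- function(matrix, pairs) {
  for (cn in c(pairs$h0, pairs$h1))
    if (!cn %in% names(matrix)) stop("missing paired column: ", cn)
  added <- character(0)
  for (k in seq_len(nrow(pairs))) {
    b <- pairs$base[k]
    matrix[[paste0(b, "_mean")]] <-
      (matrix[[pairs$h0[k]]] + matrix[[pairs$h1[k]]]) / 2
    matrix[[paste0(b, "_diff")]] <-
      matrix[[pairs$h1[k]]] - matrix[[pairs$h0[k]]]
    added <- c(added, paste0(b, c("_mean", "_diff")))
  }
  set_provenance(matrix, added, "manual")
}

# the expert formulas at both time points: ratio of oxygenation index to
# respiratory rate, and the age/RR, RR*HR, RR*HR*FiO2 products
.expert_defs <- function(h) list(
  name = paste0(c("pf_per_rr_", "age_x_rr_", "rr_x_hr_", "rr_x_hr_x_fio2_"), h),
  unit = c("mmHg/breath/min", "year*breath/min", "breath/min*beat/min",
           "breath/min*beat/min")
)

#' Expert experience features
#'
#' Adds the eight clinician-derived columns: for each of H0 and H1 the
#' oxygenation index divided by respiratory rate, age times RR, RR times HR,
#' and RR times HR times FiO2. A zero respiratory rate makes the ratio
#' feature missing for that row (to be median-imputed downstream).
#'
#' @param matrix feature `data.frame` containing `age`, `H*_pf`, `H*_rr`,
#'   `H*_hr`, `H*_fio2`.
#' @return the matrix with 8 added columns tagged `expert`; their units are
#'   stored in the `"units"` attribute.
#' @examples
#' m <- data.frame(age = 69, H0_pf = 178, H0_rr = 31, H0_hr = 134,
#'                 H0_fio2 = 0.42, H1_pf = 205, H1_rr = 27, H1_hr = 104,
#'                 H1_fio2 = 0.5)
#' expert_features(m)$pf_per_rr_H0  # 178 / 31
#' @export
expert_features <- function(matrix) {
  units <- attr(matrix, "units") %||% character(0)
  added <- character(0)
  for (h in c("H0", "H1")) {
    need <- paste0(h, "_", c("pf", "rr", "hr", "fio2"))
    miss <- setdiff(c("age", need), names(matrix))
    if (length(miss)) stop("expert features need columns: ",
                           paste(miss, collapse = ", "))
    pf <- matrix[[paste0(h, "_pf")]]; rr <- matrix[[paste0(h, "_rr")]]
    hr <- matrix[[paste0(h, "_hr")]]; fio2 <- matrix[[paste0(h, "_fio2")]]
    defs <- .expert_defs(h)
    ratio <- ifelse(rr == 0, NA_real_, pf / rr)
    if (any(rr == 0, na.rm = TRUE))
      warning("RR = 0 in ", sum(rr == 0, na.rm = TRUE),
              " rows; ratio feature set missing there")
    vals <- list(ratio, matrix$age * rr, rr * hr, rr * hr * fio2)
    for (k in 1:4) {
      matrix[[defs$name[k]]] <- vals[[k]]
      units[defs$name[k]] <- defs$unit[k]
    }
    added <- c(added, defs$name)
  }
  matrix <- set_provenance(matrix, added, "expert")
  attr(matrix, "units") <- units
  matrix
}

#' Pairwise feature crosses
#'
#' Adds one product column `<a>_x_<b>` per listed pair of numeric columns.
#'
#' @param matrix feature `data.frame`.
#' @param pair_list list of length-2 character vectors of column names.
#' @return the matrix with one added column per pair, tagged `cross`.
#' @export
feature_crosses <- function(matrix, pair_list) {
  added <- character(0)
  for (pr in pair_list) {
    if (!all(pr %in% names(matrix)))
      stop("unknown column in cross: ", paste(setdiff(pr, names(matrix)), collapse = ", "))
    nm <- paste0(pr[1], "_x_", pr[2])
    matrix[[nm]] <- matrix[[pr[1]]] * matrix[[pr[2]]]
    added <- c(added, nm)
  }
  set_provenance(matrix, added, "cross")
}

# default crosses: the variable set the expert formulas draw on
default_cross_pairs <- function(h = c("H0", "H1")) {
  vars <- unlist(lapply(h, function(x) paste0(x, "_", c("pf", "rr", "hr", "gcs", "ph"))))
  combn(vars, 2, simplify = FALSE)
}

#' Variance and Pearson feature selection
#'
#' Drops features whose variance falls below `variance_min`, then features
#' whose absolute Pearson correlation with the binary label falls below
#' `pearson_min`.
#'
#' @param matrix numeric feature `data.frame` (standardized).
#' @param labels binary 0/1 outcome vector.
#' @param variance_min variance threshold (default `1e-8`).
#' @param pearson_min absolute-correlation threshold (default `0.01`).
#' @return the filtered matrix; the `"selection_report"` attribute lists
#'   retained and dropped columns with the reason.
#' @export
select_features <- function(matrix, labels, variance_min = 1e-8,
                            pearson_min = 0.01) {
  stopifnot(is_binary01(labels), nrow(matrix) == length(labels))
  vs <- vapply(matrix, var, 0)
  drop_var <- names(matrix)[vs < variance_min | !is.finite(vs)]
  keep <- setdiff(names(matrix), drop_var)
  r <- vapply(matrix[keep], function(x) pearson_r(x, labels), 0)
  drop_r <- keep[abs(r) < pearson_min | !is.finite(r)]
  keep <- setdiff(keep, drop_r)
  if (!length(keep))
    stop("all features dropped; lower variance_min/pearson_min")
  out <- matrix[keep]
  prov <- provenance(matrix)
  attr(out, "provenance") <- prov[keep]
  attr(out, "selection_report") <- list(
    retained = keep,
    dropped_variance = drop_var,
    dropped_pearson = drop_r)
  out
}

#' Pearson correlation coefficient
#'
#' Direct covariance-over-SDs implementation, exposed so selection can be
#' audited against an independent formula.
#' @param x,y numeric vectors of equal length.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
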