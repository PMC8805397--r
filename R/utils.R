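#' @keywords internal
"_PACKAGE"

#' @useDynLib nivstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm binomial predict kmeans median sd var cor rnorm
#'   runif rbinom quantile plogis qlogis
#' @importFrom utils read.csv write.csv head combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic fan-out of one user-facing seed into independent per-stage
# seeds. Values stay below 2^31 so they are valid R integer seeds.
fanout_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, length(names))
  names(s) <- names
  s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

check_field <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

is_binary01 <- function(y) all(y %in% c(0, 1))
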