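# Synthetic ICU cohort generator.
#
# Emulates the structure of a real NIV cohort: one row per patient, static
# demographics and comorbidities, paired physiological measurements before
# NIV (H0) and after one hour of NIV (H1), and a binary failure outcome with
# roughly 30% prevalence. Marginal means/SDs of the physiological variables
# default to values typical of severe NIV candidates; the class signal lives
# mainly at H1 (failures: higher RR/HR/FiO2, lower GCS/pH/PaO2).

# reference means/SDs and physiologic bounds per paired variable
.niv_paired_vars <- list(
  gcs   = list(m0 = 14.6, s0 = 1.2,  m1 = 14.6, s1 = 1.2,  lo = 3,    hi = 15),
  sbp   = list(m0 = 137,  s0 = 26,   m1 = 127,  s1 = 23,   lo = 50,   hi = 260),
  dbp   = list(m0 = 81,   s0 = 16,   m1 = 74,   s1 = 14,   lo = 20,   hi = 160),
  hr    = list(m0 = 134,  s0 = 23,   m1 = 104,  s1 = 23,   lo = 30,   hi = 220),
  rr    = list(m0 = 31,   s0 = 7,    m1 = 27,   s1 = 7,    lo = 8,    hi = 70),
  ph    = list(m0 = 7.36, s0 = 0.11, m1 = 7.39, s1 = 0.09, lo = 6.8,  hi = 7.7),
  fio2  = list(m0 = 0.42, s0 = 0.15, m1 = 0.50, s1 = 0.16, lo = 0.21, hi = 1.0),
  paco2 = list(m0 = 57,   s0 = 26,   m1 = 54,   s1 = 22,   lo = 15,   hi = 200),
  pao2  = list(m0 = 72,   s0 = 39,   m1 = 95,   s1 = 40,   lo = 20,   hi = 400)
)

# ventilator variables only defined after NIV starts
.niv_h1_only_vars <- list(
  tidal_volume  = list(m1 = 413,  s1 = 160, lo = 50, hi = 1500),
  minute_vent   = list(m1 = 11.2, s1 = 6.6, lo = 1,  hi = 40),
  insp_pressure = list(m1 = 15,   s1 = 4,   lo = 4,  hi = 40),
  epap          = list(m1 = 6,    s1 = 2,   lo = 2,  hi = 20)
)

.niv_diagnoses <- c(
  AECOPD = 1122, Pneumonia = 652, ARDS = 197, Asthma = 70,
  SleepApnoea = 65, HeartFailure = 50, Bronchiectasis = 46, Sepsis = 44,
  PulmonaryEmbolism = 39, TBSequelae = 35, ChestWallDeformity = 22,
  ObesityHypoventilation = 6, ChronicThoracicSequelae = 2, Others = 145
)

.niv_comorbidities <- c(
  hypertension = 889 / 2495, diabetes = 493 / 2495, chronic_liver = 53 / 2495,
  chronic_kidney = 104 / 2495, chronic_heart = 201 / 2495,
  chronic_lung = 1459 / 2495, immunosuppression = 100 / 2495,
  solid_tumour = 238 / 2495
)

# class-conditional standardized mean shifts at H1 (failure minus success)
.niv_default_effects <- c(
  gcs = -0.7, sbp = -0.2, dbp = -0.2, hr = 0.7, rr = 0.8, ph = -0.6,
  fio2 = 0.7, paco2 = -0.3, pao2 = -0.7,
  minute_vent = 0.2, insp_pressure = 0.2
)

#' Specify a synthetic NIV cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' emulate a severe-ICU NIV cohort: ~30% failure prevalence, 14 diagnosis
#' categories with a long tail, and outcome-dependent H0 to H1 trajectories
#' (failures deteriorate: respiratory rate, heart rate and FiO2 rise while
#' GCS, pH and PaO2 fall relative to successes).
#'
#' @param n_patients number of rows to generate.
#' @param failure_rate expected fraction of NIV failures, strictly in (0,1).
#' @param diagnosis_distribution named probability vector over diagnosis
#'   categories; must sum to 1.
#' @param effect_sizes named vector of standardized mean differences
#'   (failure minus success) applied at H1; names are base variable names
#'   such as `"rr"` or `"pao2"`.
#' @param h0_effect_fraction fraction of each H1 effect also present at H0
#'   (failures already differ somewhat before NIV starts).
#' @param h0h1_correlation within-patient latent correlation between the H0
#'   and H1 draws of the same variable.
#' @param missing_rate completely-at-random missingness fraction applied to
#'   physiological measurement cells.
#' @param outlier_rate fraction of physiological cells replaced by implausible
#'   spikes 6-9 SDs from the variable mean (to exercise outlier masking).
#' @param n_isolated_minority number of isolated minority (failure) points to
#'   plant far from every other minority point.
#' @param seed integer RNG seed; identical spec + seed gives an identical table.
#' @return an object of class `niv_cohort_spec`.
#' @seealso [generate_cohort()], [plant_isolated_minority()]
#' @export
cohort_spec <- function(n_patients = 2495,
                        failure_rate = 740 / 2495,
                        diagnosis_distribution = .niv_diagnoses / sum(.niv_diagnoses),
                        effect_sizes = .niv_default_effects,
                        h0_effect_fraction = 0.4,
                        h0h1_correlation = 0.6,
                        missing_rate = 0.02,
                        outlier_rate = 0.005,
                        n_isolated_minority = 0L,
                        seed = 1L) {
  check_field(is.numeric(n_patients) && length(n_patients) == 1 &&
                n_patients >= 2 && n_patients == floor(n_patients),
              "n_patients", "must be a positive integer >= 2")
  check_field(is.numeric(failure_rate) && failure_rate > 0 && failure_rate < 1,
              "failure_rate", "must be strictly between 0 and 1")
  check_field(!is.null(names(diagnosis_distribution)) &&
                all(diagnosis_distribution >= 0) &&
                abs(sum(diagnosis_distribution) - 1) < 1e-9,
              "diagnosis_distribution", "must be named, non-negative and sum to 1")
  known <- c(names(.niv_paired_vars), names(.niv_h1_only_vars))
  check_field(all(names(effect_sizes) %in% known), "effect_sizes",
              paste("names must be among:", paste(known, collapse = ", ")))
  check_field(missing_rate >= 0 && missing_rate < 1, "missing_rate", "must be in [0,1)")
  check_field(outlier_rate >= 0 && outlier_rate < 1, "outlier_rate", "must be in [0,1)")
  check_field(h0h1_correlation > -1 && h0h1_correlation < 1,
              "h0h1_correlation", "must be in (-1,1)")
  check_field(n_isolated_minority >= 0 &&
                n_isolated_minority <= n_patients * failure_rate,
              "n_isolated_minority",
              "must be non-negative and not exceed the expected minority count")
  structure(list(n_patients = as.integer(n_patients), failure_rate = failure_rate,
                 diagnosis_distribution = diagnosis_distribution,
                 effect_sizes = effect_sizes,
                 h0_effect_fraction = h0_effect_fraction,
                 h0h1_correlation = h0h1_correlation,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 n_isolated_minority = as.integer(n_isolated_minority),
                 seed = as.integer(seed)),
            class = "niv_cohort_spec")
}

#' @export
print.niv_cohort_spec <- function(x, ...) {
  cat("<niv_cohort_spec>", x$n_patients, "patients, failure rate",
      signif(x$failure_rate, 3), ", seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic NIV cohort table
#'
#' Draws one row per patient. Outcome labels are drawn first as
#' Bernoulli(`failure_rate`); physiological variables are then drawn from
#' truncated Gaussians whose class-conditional means differ by the configured
#' standardized effect sizes at H1 (attenuated at H0). Because the two
#' classes share a covariance structure, the implied posterior
#' P(failure | features) is exactly logistic, while the configured effect
#' sizes are realized as mean differences by construction. The
#' `H*_pf` (PaO2/FiO2, "oxygenation index") columns are computed as the
#' exact ratio of the generated PaO2 and FiO2 columns.
#'
#' @param spec a [cohort_spec()] object.
#' @return a `data.frame` with columns `patient_id`, static fields
#'   (`age`, `sex`, `apache`, `diagnosis`, comorbidity flags), paired
#'   `H0_*`/`H1_*` measurements, H1-only ventilator variables, and the
#'   binary outcome `niv_failure`.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_patients = 200, seed = 7))
#' mean(tab$niv_failure)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "niv_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    y <- rbinom(n, 1, spec$failure_rate)
    # guarantee both classes (contractual invariant) at tiny n
    if (all(y == 0)) y[sample.int(n, 1)] <- 1
    if (all(y == 1)) y[sample.int(n, 1)] <- 0
    f <- spec$failure_rate
    # symmetric shifts keep the marginal mean at its reference value
    shift_of <- function(e) ifelse(y == 1, e * (1 - f), -e * f)

    out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out$age <- pmin(pmax(rnorm(n, 69, 14), 18), 100)
    out$sex <- rbinom(n, 1, 1794 / 2495)
    out$apache <- pmin(pmax(rnorm(n, 16 + 2.5 * (y - mean(y)), 5), 0), 71)
    out$diagnosis <- sample(names(spec$diagnosis_distribution), n, replace = TRUE,
                            prob = spec$diagnosis_distribution)
    for (cm in names(.niv_comorbidities))
      out[[cm]] <- rbinom(n, 1, .niv_comorbidities[[cm]])

    rho <- spec$h0h1_correlation
    for (v in names(.niv_paired_vars)) {
      p <- .niv_paired_vars[[v]]
      e1 <- spec$effect_sizes[v]; if (is.na(e1)) e1 <- 0
      e0 <- e1 * spec$h0_effect_fraction
      z0 <- rnorm(n)
      z1 <- rho * z0 + sqrt(1 - rho^2) * rnorm(n)
      out[[paste0("H0_", v)]] <-
        pmin(pmax(p$m0 + p$s0 * (z0 + shift_of(e0)), p$lo), p$hi)
      out[[paste0("H1_", v)]] <-
        pmin(pmax(p$m1 + p$s1 * (z1 + shift_of(e1)), p$lo), p$hi)
    }
    for (v in names(.niv_h1_only_vars)) {
      p <- .niv_h1_only_vars[[v]]
      e1 <- spec$effect_sizes[v]; if (is.na(e1)) e1 <- 0
      out[[paste0("H1_", v)]] <-
        pmin(pmax(p$m1 + p$s1 * (rnorm(n) + shift_of(e1)), p$lo), p$hi)
    }

    meas <- measurement_columns(out)
    base_meas <- setdiff(meas, c("H0_pf", "H1_pf"))  # pf computed below
    # implausible spikes, then MCAR missingness, then the exact ratio column
    if (spec$outlier_rate > 0) {
      for (cn in base_meas) {
        hit <- runif(n) < spec$outlier_rate
        if (any(hit)) {
          mu <- mean(out[[cn]]); s <- sd(out[[cn]])
          out[[cn]][hit] <- mu + sample(c(-1, 1), sum(hit), TRUE) *
            runif(sum(hit), 6, 9) * s
        }
      }
    }
    if (spec$missing_rate > 0)
      for (cn in base_meas)
        out[[cn]][runif(n) < spec$missing_rate] <- NA_real_
    out$H0_pf <- out$H0_pao2 / out$H0_fio2
    out$H1_pf <- out$H1_pao2 / out$H1_fio2
    out$niv_failure <- y
    if (spec$n_isolated_minority > 0)
      out <- plant_isolated_minority(out, spec$n_isolated_minority,
                                     separation = 10,
                                     seed = spec$seed + 777L)
    out
  })
}

#' Names of the physiological measurement columns of a cohort table
#' @param table a cohort `data.frame`.
#' @return character vector of `H0_*`/`H1_*` column names.
#' @export
measurement_columns <- function(table) {
  grep("^H[01]_", names(table), value = TRUE)
}

#' H0/H1 column pairing of a cohort table
#'
#' Derives the paired-feature map: every `H0_<base>` column matched with its
#' `H1_<base>` counterpart.
#'
#' @param table a cohort `data.frame`.
#' @return a `data.frame` with columns `h0`, `h1`, `base`.
#' @export
paired_feature_map <- function(table) {
  h0 <- grep("^H0_", names(table), value = TRUE)
  base <- sub("^H0_", "", h0)
  h1 <- paste0("H1_", base)
  missing <- h1[!h1 %in% names(table)]
  if (length(missing))
    stop("H0 columns without H1 counterpart: ", paste(missing, collapse = ", "))
  data.frame(h0 = h0, h1 = h1, base = base, stringsAsFactors = FALSE)
}

#' Plant isolated minority points
#'
#' Appends `n` minority (failure) rows whose nearest minority neighbour, in
#' standardized Euclidean distance over the physiological columns, is farther
#' than `separation`. Used to exercise the isolated-instance removal step of
#' the modified SMOTE oversampler.
#'
#' @param table a cohort `data.frame` with at least one minority row.
#' @param n number of points to plant (0 returns the table unchanged).
#' @param separation required minimal distance (in pooled-SD units).
#' @param seed integer RNG seed.
#' @return the augmented cohort table; planted rows have ids `ISO####`.
#' @export
plant_isolated_minority <- function(table, n, separation = 10, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(table)
  if (!any(table$niv_failure == 1)) stop("table has no minority row")
  meas <- measurement_columns(table)
  mu <- vapply(table[meas], function(x) mean(x, na.rm = TRUE), 0)
  sdv <- vapply(table[meas], function(x) sd(x, na.rm = TRUE), 0)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  d <- length(meas)

  with_seed(seed, {
    for (attempt in 1:25) {
      radius <- separation * (2 + attempt)
      z <- matrix(rnorm(n * d), n, d)
      z <- z / sqrt(rowSums(z^2)) * radius          # points on a remote sphere
      planted <- table[rep(which(table$niv_failure == 1)[1], n), , drop = FALSE]
      planted$patient_id <- sprintf("ISO%04d", seq_len(n))
      for (j in seq_along(meas))
        planted[[meas[j]]] <- mu[j] + sdv[j] * z[, j]
      # keep the oxygenation-index ratio invariant exact
      planted$H0_pf <- planted$H0_pao2 / planted$H0_fio2
      planted$H1_pf <- planted$H1_pao2 / planted$H1_fio2
      planted$niv_failure <- 1
      aug <- rbind(table, planted)
      if (min(.min_minority_nn_dist(aug, meas, mu, sdv,
                                    which(aug$patient_id %in% planted$patient_id))) >
          separation)
        return(aug)
    }
    stop("could not plant ", n, " isolated minority points at separation ",
         separation)
  })
}

# for each planted row: distance to its nearest other minority row
.min_minority_nn_dist <- function(table, meas, mu, sdv, planted_idx) {
  Z <- scale(as.matrix(table[meas]), center = mu, scale = sdv)
  Z[is.na(Z)] <- 0
  mino <- which(table$niv_failure == 1)
  vapply(planted_idx, function(i) {
    others <- setdiff(mino, i)
    min(sqrt(colSums((t(Z[others, , drop = FALSE]) - Z[i, ])^2)))
  }, 0)
}

#' Write / read a cohort table as CSV
#'
#' Plain-CSV persistence using the `H0_*`/`H1_*` naming convention and a
#' 0/1 `niv_failure` outcome column.
#'
#' @param table a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the `data.frame`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"niv_failure" %in% names(tab)) stop("not a cohort CSV: no niv_failure column")
  tab
}
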