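# End-to-end orchestration: cohort -> split -> clean -> feature families
# (manual temporal, expert, crosses, deep) -> scale -> select -> oversample
# -> stack -> metrics -> explanations. One global seed fans out to
# per-stage seeds; re-running a config reproduces every numeric output.

# second-stage scaler for generated features: median-impute + z-score with
# training statistics (outlier masking already happened on the base columns)
fit_scaler <- function(train_df, cols) {
  st <- lapply(cols, function(cn) {
    x <- train_df[[cn]]
    med <- median(x, na.rm = TRUE)
    if (!is.finite(med)) stop("feature entirely missing in training split: ", cn)
    x <- impute_median(x, med)
    list(median = med, center = mean(x), scale = pop_sd(x))
  })
  names(st) <- cols
  st[vapply(st, function(s) is.finite(s$scale) && s$scale > 0, TRUE)]
}

apply_scaler <- function(scaler, df) {
  out <- df[intersect(names(scaler), names(df))]
  for (cn in names(scaler))
    out[[cn]] <- zscore(impute_median(df[[cn]], scaler[[cn]]$median),
                        scaler[[cn]]$center, scaler[[cn]]$scale)
  out
}

#' Assemble the model-ready feature matrices
#'
#' Applies the full feature chain with training-split-only statistics:
#' 3-sigma outlier masking and median imputation of the physiological
#' columns, the three generated feature families (toggleable), one-hot
#' diagnosis encoding, z-scoring, and variance + Pearson selection.
#'
#' @param train,test cohort `data.frame`s from [split_train_test()].
#' @param use_manual,use_expert,use_cross,use_deep stage toggles for the
#'   temporal mean/diff, expert-formula, pairwise-cross and autoencoder
#'   feature families (the ablation arms).
#' @param ae_spec an [autoencoder_spec()] for the deep features.
#' @param pre_spec a [preprocess_spec()].
#' @param variance_min,pearson_min selection thresholds.
#' @param seed integer seed (autoencoder fit).
#' @return list with `train_X`, `train_y`, `test_X`, `test_y` (numeric
#'   `data.frame`s with provenance attributes), `autoencoder`, `scaler`,
#'   `selection_report`.
#' @export
build_features <- function(train, test,
                           use_manual = TRUE, use_expert = TRUE,
                           use_cross = TRUE, use_deep = TRUE,
                           ae_spec = autoencoder_spec(),
                           pre_spec = preprocess_spec(),
                           variance_min = 1e-8, pearson_min = 0.01,
                           seed = 1L) {
  pairs <- paired_feature_map(train)
  meas <- measurement_columns(train)
  static_num <- intersect(c("age", "apache"), names(train))
  flags <- intersect(c("sex", names(.niv_comorbidities)), names(train))

  # stage 1: mask outliers + impute on raw scale, training statistics only
  clean <- lapply(c(meas, static_num), function(cn) {
    x <- train[[cn]]
    mask <- detect_outliers(x, pre_spec$outlier_sigma)
    xm <- x; xm[mask] <- NA
    med <- median(xm, na.rm = TRUE)
    list(mean = mean(x, na.rm = TRUE), sd = pop_sd(x), median = med)
  })
  names(clean) <- c(meas, static_num)
  clean_apply <- function(tab) {
    for (cn in names(clean)) {
      st <- clean[[cn]]
      x <- tab[[cn]]
      x[!is.na(x) & abs(x - st$mean) > pre_spec$outlier_sigma * st$sd] <- NA
      tab[[cn]] <- impute_median(x, st$median)
    }
    tab
  }
  ctr <- clean_apply(train); cte <- clean_apply(test)

  gen <- function(tab) {
    m <- tab[c(static_num, meas)]
    m <- set_provenance(m, names(m), "raw")
    if (use_manual) m <- temporal_mean_diff(m, pairs)
    if (use_expert) m <- expert_features(m)
    if (use_cross) m <- feature_crosses(m, default_cross_pairs())
    m
  }
  gtr <- gen(ctr); gte <- gen(cte)
  prov <- provenance(gtr)

  scaler <- fit_scaler(gtr, names(gtr))
  str_ <- apply_scaler(scaler, gtr); ste_ <- apply_scaler(scaler, gte)
  prov <- prov[names(str_)]

  ae <- NULL
  if (use_deep) {
    # autoencoder consumes the standardized paired columns, fit on train only
    ok <- pairs$h0 %in% names(str_) & pairs$h1 %in% names(str_)
    pr <- pairs[ok, , drop = FALSE]
    sp <- ae_spec
    sp$latent_dim <- min(sp$latent_dim, nrow(pr))
    sp$seed <- seed
    ae <- fit_autoencoder(paired_sequences(str_, pr), sp)
    dtr <- encode_features(ae, paired_sequences(str_, pr))
    dte <- encode_features(ae, paired_sequences(ste_, pr))
    # scale the latent columns with training statistics too
    dscaler <- fit_scaler(dtr, names(dtr))
    dtr <- apply_scaler(dscaler, dtr); dte <- apply_scaler(dscaler, dte)
    str_ <- cbind(str_, dtr); ste_ <- cbind(ste_, dte)
    prov <- c(prov, stats::setNames(rep("deep", ncol(dtr)), names(dtr)))
  }

  # binary flags and diagnosis indicators pass through unscaled
  add_flags <- function(Xd, tab) {
    for (fl in flags) Xd[[fl]] <- tab[[fl]]
    if ("diagnosis" %in% names(tab)) {
      oh <- onehot(tab$diagnosis, levels_map = dx_levels,
                   threshold = pre_spec$rare_category_threshold,
                   prefix = "dx")
      Xd <- cbind(Xd, oh)
    }
    Xd
  }
  dx_levels <- if ("diagnosis" %in% names(train))
    attr(onehot(train$diagnosis, threshold = pre_spec$rare_category_threshold,
                prefix = "dx"), "levels_map")
  str_ <- add_flags(str_, train); ste_ <- add_flags(ste_, test)
  prov <- c(prov, stats::setNames(rep("raw", ncol(str_) - length(prov)),
                                  setdiff(names(str_), names(prov))))
  attr(str_, "provenance") <- prov[names(str_)]

  sel <- select_features(str_, train$niv_failure, variance_min, pearson_min)
  keep <- names(sel)
  out_te <- ste_[keep]
  attr(out_te, "provenance") <- provenance(sel)
  list(train_X = sel, train_y = train$niv_failure,
       test_X = out_te, test_y = test$niv_failure,
       autoencoder = ae, scaler = scaler,
       selection_report = attr(sel, "selection_report"))
}

#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()]; any field can be
#' overridden. Stage toggles (`features$use_*`, `oversample$method`) express
#' the ablation arms.
#'
#' @param n_patients cohort size for the synthetic cohort.
#' @param seed global seed fanned out to all stages.
#' @param out_dir output directory (`NULL` for no artifacts).
#' @return a nested list of class `niv_config`.
#' @export
default_config <- function(n_patients = 1000L, seed = 1L, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohort = list(n_patients = as.integer(n_patients), csv = NULL),
    split = list(fraction = 0.8, stratify = FALSE),
    features = list(use_manual = TRUE, use_expert = TRUE, use_cross = TRUE,
                    use_deep = TRUE, latent_dim = 8L, hidden_units = 32L,
                    epochs = 30L, variance_min = 1e-8, pearson_min = 0.01),
    oversample = list(method = "modified", target_ratio = 1.0, m = 5L,
                      n_clusters = "auto"),
    stack = list(n_folds = 5L, decision_threshold = 0.5,
                 rf_trees = 100L, gbdt_trees = 100L),
    explain = list(enabled = TRUE, max_rows = 25L)
  ), class = "niv_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with (a subset of) the [default_config()] fields.
#' @return a `niv_config` list merged over the defaults.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (top in names(user)) {
    if (is.list(cfg[[top]]) && is.list(user[[top]]))
      for (k in names(user[[top]])) cfg[[top]][[k]] <- user[[top]][[k]]
    else cfg[[top]] <- user[[top]]
  }
  cfg
}

#' Run the full prediction pipeline
#'
#' Generates (or loads) a cohort, splits it, engineers features, oversamples
#' the training split, fits the stacking classifier, scores the held-out
#' split and, optionally, computes global feature importance. When
#' `config$out_dir` is set, writes `metrics.json`, `config.json`,
#' `manifest.json`, `selection.json`, `oversample_provenance.csv` and
#' `importance.csv`.
#'
#' @param config a [default_config()]-shaped list.
#' @return an object of class `niv_run_report`: `metrics` (one metrics row
#'   per evaluated model), `stack`, `features`, `oversample_report`,
#'   `importance`, `seeds`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_config(n_patients = 400, seed = 3))
#' rep$metrics
#' }
#' @export
run_pipeline <- function(config = default_config()) {
  seeds <- fanout_seeds(config$seed,
                        c("cohort", "split", "features", "oversample",
                          "stack", "explain"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort$csv)) read_cohort(config$cohort$csv)
    else generate_cohort(cohort_spec(n_patients = config$cohort$n_patients,
                                     seed = seeds[["cohort"]]))
  })
  sp <- stage("split",
    split_train_test(cohort, config$split$fraction, seeds[["split"]],
                     config$split$stratify))
  fe <- config$features
  feats <- stage("features",
    build_features(sp$train, sp$test,
                   use_manual = fe$use_manual, use_expert = fe$use_expert,
                   use_cross = fe$use_cross, use_deep = fe$use_deep,
                   ae_spec = autoencoder_spec(latent_dim = fe$latent_dim,
                                              hidden_units = fe$hidden_units,
                                              epochs = fe$epochs),
                   variance_min = fe$variance_min,
                   pearson_min = fe$pearson_min,
                   seed = seeds[["features"]]))
  os <- stage("oversample",
    oversample_baseline(feats$train_X, feats$train_y,
                        method = config$oversample$method,
                        spec = oversample_spec(
                          m = config$oversample$m,
                          n_clusters = config$oversample$n_clusters,
                          target_ratio = config$oversample$target_ratio,
                          seed = seeds[["oversample"]])))
  st <- stage("stack", {
    learners <- default_learners(rf_trees = config$stack$rf_trees,
                                 gbdt_trees = config$stack$gbdt_trees)
    fit_stack(os$X, os$y,
              stack_spec(learners = learners, n_folds = config$stack$n_folds,
                         decision_threshold = config$stack$decision_threshold,
                         seed = seeds[["stack"]]))
  })
  metrics <- stage("evaluate", {
    rows <- list(metrics_row(feats$test_y,
                             predict_proba(st, feats$test_X),
                             threshold = config$stack$decision_threshold,
                             id = "stack"))
    for (nm in names(st$base))
      rows <- c(rows, list(metrics_row(
        feats$test_y,
        st$spec$learners[[nm]]$predict_proba(st$base[[nm]], feats$test_X),
        threshold = config$stack$decision_threshold, id = nm)))
    do.call(rbind, rows)
  })
  importance <- NULL
  if (isTRUE(config$explain$enabled)) {
    importance <- stage("explain",
      explain_global(st$base$gbdt, feats$test_X,
                     max_rows = config$explain$max_rows))
  }
  report <- structure(list(metrics = metrics, stack = st, features = feats,
                           oversample_report = os$report,
                           importance = importance, seeds = seeds,
                           config = config),
                      class = "niv_run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.niv_run_report <- function(x, ...) {
  cat("<niv_run_report> held-out metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$metrics, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(seeds = as.list(report$seeds),
                            r_version = R.version.string,
                            package_version =
                              as.character(utils::packageVersion("nivstack"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(report$features$selection_report,
                       file.path(out_dir, "selection.json"))
  prov <- report$oversample_report$provenance
  if (!is.null(prov))
    write.csv(prov[c("cluster", "seed_index", "u")],
              file.path(out_dir, "oversample_provenance.csv"),
              row.names = FALSE)
  if (!is.null(report$importance))
    write.csv(report$importance, file.path(out_dir, "importance.csv"),
              row.names = FALSE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort CSV), `run`/`train`
#' (full pipeline), `benchmark-oversamplers`, `benchmark-classifiers`.
#' Common options: `--config <json>`, `--seed <int>`, `--out <dir>`,
#' `--n <patients>`. Invoked by the `inst/cli/nivstack.R` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: nivstack <simulate|run|benchmark-oversamplers|",
            "benchmark-classifiers> [--config f.json] [--seed n] ",
            "[--out dir] [--n patients]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(opt("--config"))) read_config(opt("--config"))
         else default_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--n"))) cfg$cohort$n_patients <- as.integer(opt("--n"))
  cfg$out_dir <- opt("--out", cfg$out_dir %||% "nivstack_out")

  if (cmd == "simulate") {
    tab <- generate_cohort(cohort_spec(n_patients = cfg$cohort$n_patients,
                                       seed = cfg$seed))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(tab, file.path(cfg$out_dir, "cohort.csv"))
    message("wrote ", file.path(cfg$out_dir, "cohort.csv"))
  } else if (cmd %in% c("run", "train", "evaluate", "explain")) {
    rep <- run_pipeline(cfg)
    print(rep)
  } else if (cmd %in% c("benchmark-oversamplers", "benchmark-classifiers")) {
    seeds <- fanout_seeds(cfg$seed, c("cohort", "split", "features", "bench"))
    cohort <- if (!is.null(cfg$cohort$csv)) read_cohort(cfg$cohort$csv)
      else generate_cohort(cohort_spec(n_patients = cfg$cohort$n_patients,
                                       seed = seeds[["cohort"]]))
    sp <- split_train_test(cohort, cfg$split$fraction, seeds[["split"]])
    fx <- build_features(sp$train, sp$test, seed = seeds[["features"]])
    tabres <- if (cmd == "benchmark-oversamplers")
      benchmark_oversamplers(fx$train_X, fx$train_y, fx$test_X, fx$test_y,
                             spec = oversample_spec(seed = seeds[["bench"]]))
    else {
      os <- oversample(fx$train_X, fx$train_y,
                       oversample_spec(seed = seeds[["bench"]]))
      benchmark_classifiers(os$X, os$y, fx$test_X, fx$test_y,
                            seed = seeds[["bench"]])
    }
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tabres, file.path(cfg$out_dir, paste0(cmd, ".csv")),
              row.names = FALSE)
    print(tabres, row.names = FALSE)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
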