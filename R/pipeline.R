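#' Experiment configuration
#'
#' Bundles every stage setting of the end-to-end pipeline. The defaults are
#' the study configuration: 200/302/98 simulated samples over 934 bands
#' (400-1100 nm), 7:3 stratified split, MSC, BL-SMOTE balancing (k = 5),
#' CARS selection (50 Monte Carlo runs, 5-fold CV) and MRSA-tuned RBF-SVM
#' (population 20, 50 iterations, `c, g` in `[2^-2, 2^8]`). The master
#' `seed` derives an independent sub-seed for every stage, so switching one
#' stage never perturbs another stage's random stream. Unknown settings are
#' an error.
#'
#' @param input_csv Optional path to a spectra CSV; when `NULL` the
#'   synthetic generator supplies the data.
#' @param class_counts,n_bands,band_range Generator settings ([sim_config()]).
#' @param crop Modelling window in nm.
#' @param train_fraction Stratified split ratio.
#' @param msc Apply multiplicative scatter correction (reference fitted on
#'   the training set).
#' @param oversample_method One of none/ros/smote/blsmote/adasyn.
#' @param k_neighbors Neighbourhood size for the oversamplers.
#' @param varselect_method One of none/cars/spa.
#' @param cars_runs CARS Monte Carlo runs.
#' @param spa_range SPA cardinality range `c(min, max)`.
#' @param folds Cross-validation folds used throughout.
#' @param model `"svm"` or `"plsda"`.
#' @param optimizer `"mrsa"`, `"rsa"`, `"ga"`, `"pso"`, `"grid"` or
#'   `"none"` (fixed `svm_c`/`svm_g`).
#' @param n_candidates,max_iters Optimizer population size and budget.
#' @param svm_c,svm_g Fixed SVM parameters when `optimizer = "none"`.
#' @param max_lv PLS-DA latent-variable cap.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(input_csv = NULL,
                              class_counts = c(200, 302, 98),
                              n_bands = 934,
                              band_range = c(400, 1100),
                              crop = c(400, 1100),
                              train_fraction = 0.7,
                              msc = TRUE,
                              oversample_method = "blsmote",
                              k_neighbors = 5,
                              varselect_method = "cars",
                              cars_runs = 50,
                              spa_range = c(5, 20),
                              folds = 5,
                              model = "svm",
                              optimizer = "mrsa",
                              n_candidates = 20,
                              max_iters = 50,
                              svm_c = 10,
                              svm_g = 16,
                              max_lv = 15,
                              seed = 1L) {
  oversample_method <- match.arg(oversample_method,
                                 c("none", "ros", "smote", "blsmote", "adasyn"))
  varselect_method <- match.arg(varselect_method, c("none", "cars", "spa"))
  model <- match.arg(model, c("svm", "plsda"))
  optimizer <- match.arg(optimizer,
                         c("mrsa", "rsa", "ga", "pso", "grid", "none"))
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

stage_log <- function(quiet, stage, seed, detail, t0) {
  if (quiet) return(invisible())
  message(sprintf("[%-10s] seed=%-10s %s (%.2fs)", stage,
                  ifelse(is.na(seed), "-", seed), detail,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full detection pipeline
#'
#' Executes simulate/load, crop, stratified split, MSC (reference fitted on
#' the training rows only), oversampling of the training set, wavelength
#' selection, SVM parameter tuning, final training, and evaluation on the
#' untouched test set. Test rows are read exactly once, at the final
#' prediction.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory for artifacts (train/test CSV, selected
#'   bands JSON, tuning trace CSV, metrics JSON) sufficient to re-run the
#'   evaluation without re-training.
#' @param quiet Suppress the one-line-per-stage log.
#' @return An `experiment_result` list: `metrics` (a [report()]),
#'   `confusion`, `svm_params`, `tuning`, `selection`, `model`, `train`,
#'   `test`, `config`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  ms <- cfg$seed
  t0 <- Sys.time()
  data <- if (!is.null(cfg$input_csv)) {
    read_spectra_csv(cfg$input_csv)
  } else {
    generate_spectra(sim_config(class_counts = cfg$class_counts,
                                n_bands = cfg$n_bands,
                                band_range = cfg$band_range,
                                seed = derive_seed(ms, 1L)))
  }
  stage_log(quiet, "data", derive_seed(ms, 1L),
            sprintf("%d x %d", nrow(data), length(wavelengths(data))), t0)

  t0 <- Sys.time()
  data <- crop_wavelengths(data, cfg$crop[1], cfg$crop[2])
  stage_log(quiet, "crop", NA, sprintf("%d bands kept", length(wavelengths(data))), t0)

  t0 <- Sys.time()
  sp <- stratified_split(data, cfg$train_fraction, seed = derive_seed(ms, 3L))
  train <- sp$train; test <- sp$test
  stage_log(quiet, "split", derive_seed(ms, 3L),
            sprintf("train %d / test %d", nrow(train), nrow(test)), t0)

  if (isTRUE(cfg$msc)) {
    t0 <- Sys.time()
    ref <- msc_fit(train)
    train <- msc_apply(train, ref)
    test <- msc_apply(test, ref)
    stage_log(quiet, "msc", NA, "train-fitted reference applied", t0)
  }

  t0 <- Sys.time()
  train_bal <- oversample(train, cfg$oversample_method, k = cfg$k_neighbors,
                          m = cfg$k_neighbors, seed = derive_seed(ms, 5L))
  stage_log(quiet, "oversample", derive_seed(ms, 5L),
            sprintf("%s: %d -> %d rows", cfg$oversample_method, nrow(train),
                    nrow(train_bal)), t0)

  t0 <- Sys.time()
  selection <- switch(cfg$varselect_method,
    none = NULL,
    cars = cars_select(train_bal, runs = cfg$cars_runs, folds = cfg$folds,
                       seed = derive_seed(ms, 6L)),
    spa = spa_select(train_bal, n_min = cfg$spa_range[1],
                     n_max = cfg$spa_range[2], folds = cfg$folds,
                     seed = derive_seed(ms, 6L))
  )
  sel_idx <- if (is.null(selection)) seq_along(wavelengths(train_bal)) else
    selection$selected_indices
  Xtr <- spectra_matrix(train_bal)[, sel_idx, drop = FALSE]
  ytr <- spectra_labels(train_bal)
  stage_log(quiet, "varselect", derive_seed(ms, 6L),
            sprintf("%s: %d bands", cfg$varselect_method, length(sel_idx)), t0)

  t0 <- Sys.time()
  tuning <- NULL
  if (cfg$model == "plsda") {
    model <- plsda_train(Xtr, ytr, max_lv = cfg$max_lv, folds = cfg$folds,
                         seed = derive_seed(ms, 7L))
    pars <- NULL
    stage_log(quiet, "train", derive_seed(ms, 7L),
              sprintf("PLS-DA with %d LVs", model$ncomp), t0)
  } else {
    pars <- switch(cfg$optimizer,
      none = svm_params(cfg$svm_c, cfg$svm_g),
      grid = grid_search_cg(Xtr, ytr, 2^seq(-2, 8, by = 2), 2^seq(-2, 8, by = 2),
                            folds = cfg$folds, seed = derive_seed(ms, 7L)),
      {
        tuning <- tune_svm(Xtr, ytr, optimizer = cfg$optimizer,
                           params = rsa_params(n_candidates = cfg$n_candidates,
                                               max_iters = cfg$max_iters,
                                               seed = derive_seed(ms, 7L)),
                           folds = cfg$folds)
        tuning$params
      }
    )
    stage_log(quiet, "tune", derive_seed(ms, 7L),
              sprintf("%s: c=%.4g g=%.4g", cfg$optimizer, pars$c, pars$g), t0)
    t0 <- Sys.time()
    model <- svm_train(Xtr, ytr, pars)
    stage_log(quiet, "train", NA, "RBF-SVM fitted", t0)
  }

  t0 <- Sys.time()
  Xte <- spectra_matrix(test)[, sel_idx, drop = FALSE]
  pred <- predict(model, Xte)
  cm <- confusion(spectra_labels(test), pred)
  metrics <- report(cm)
  stage_log(quiet, "evaluate", NA,
            sprintf("test accuracy %.2f%%", 100 * metrics$accuracy), t0)

  out <- structure(list(
    metrics = metrics, confusion = cm, svm_params = pars, tuning = tuning,
    selection = selection, model = model, train = train_bal, test = test,
    config = cfg
  ), class = "experiment_result")
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(res$train, file.path(out_dir, "train_balanced.csv"))
  write_spectra_csv(res$test, file.path(out_dir, "test.csv"))
  if (!is.null(res$selection)) {
    jsonlite::write_json(list(indices = res$selection$selected_indices,
                              wavelengths = res$selection$selected_wavelengths),
                         file.path(out_dir, "bands.json"), auto_unbox = FALSE)
  }
  if (!is.null(res$tuning)) {
    readr::write_csv(tidy(res$tuning$result),
                     file.path(out_dir, "trace.csv"))
  }
  m <- res$metrics
  jsonlite::write_json(list(
    confusion = unclass(res$confusion),
    accuracy = m$accuracy, macro_recall = m$macro_recall,
    macro_precision = m$macro_precision, macro_f1 = m$macro_f1,
    kappa_paper = m$kappa_paper, kappa_cohen = m$kappa_cohen,
    printed = list(
      accuracy = sprintf("%.2f", round_half_up(100 * m$accuracy, 2)),
      recall = sprintf("%.2f", round_half_up(100 * m$macro_recall, 2)),
      precision = sprintf("%.2f", round_half_up(100 * m$macro_precision, 2)),
      f1 = sprintf("%.2f", round_half_up(100 * m$macro_f1, 2)),
      kappa = sprintf("%.2f", round_half_up(100 * m$kappa_paper, 2))
    )
  ), file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Compare tuning optimizers on one shared dataset
#'
#' Prepares the data once (simulate/load through wavelength selection) and
#' then tunes, trains and evaluates an SVM per optimizer on identical
#' training/test matrices and identical CV folds, so the comparison is
#' paired.
#'
#' @param cfg An [experiment_config()].
#' @param methods Optimizers to compare.
#' @return A tibble with one row per method: `method`, `c`, `g`,
#'   `cv_fitness`, `accuracy`, `recall`, `precision`, `f1`, `kappa`
#'   (test-set macro metrics, proportions).
#' @export
compare_optimizers <- function(cfg = experiment_config(),
                               methods = c("mrsa", "rsa", "ga", "pso")) {
  if (length(methods) < 2) abort("need at least 2 methods to compare.")
  base_cfg <- cfg
  base_cfg$optimizer <- "none"
  prep <- run_experiment(base_cfg, quiet = TRUE)
  sel_idx <- if (is.null(prep$selection)) {
    seq_along(wavelengths(prep$train))
  } else prep$selection$selected_indices
  Xtr <- spectra_matrix(prep$train)[, sel_idx, drop = FALSE]
  ytr <- spectra_labels(prep$train)
  Xte <- spectra_matrix(prep$test)[, sel_idx, drop = FALSE]
  yte <- spectra_labels(prep$test)
  purrr::map_dfr(methods, function(mth) {
    tn <- tune_svm(Xtr, ytr, optimizer = mth,
                   params = rsa_params(n_candidates = cfg$n_candidates,
                                       max_iters = cfg$max_iters,
                                       seed = derive_seed(cfg$seed, 7L)),
                   folds = cfg$folds)
    fit <- svm_train(Xtr, ytr, tn$params)
    m <- report(confusion(yte, predict(fit, Xte)))
    tibble(method = mth, c = tn$params$c, g = tn$params$g,
           cv_fitness = 1 - tn$result$best_fitness,
           accuracy = m$accuracy, recall = m$macro_recall,
           precision = m$macro_precision, f1 = m$macro_f1,
           kappa = m$kappa_paper)
  })
}
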