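#' RBF-SVM penalty and kernel parameters
#'
#' Both parameters live in the tuning box `[2^-2, 2^8]`. `g` is used directly
#' as the RBF coefficient in `K(u, v) = exp(-g ||u - v||^2)`.
#'
#' @param c Penalty (cost) parameter.
#' @param g Kernel width coefficient.
#' @return An `svm_params` list.
#' @export
svm_params <- function(c, g) {
  lo <- 2^-2; hi <- 2^8
  if (c < lo || c > hi || g < lo || g > hi) {
    abort(sprintf("c and g must lie in [%g, %g].", lo, hi))
  }
  structure(list(c = c, g = g), class = "svm_params")
}

#' @export
print.svm_params <- function(x, ...) {
  cat(sprintf("# SVM parameters: c = %.4g, g = %.4g\n", x$c, x$g))
  invisible(x)
}

resolve_xy_matrix <- function(x, y) {
  d <- resolve_xy(x, y)
  d$y <- droplevels(factor(d$y))
  d
}

#' Train a multiclass RBF-SVM
#'
#' One-vs-one decomposition with majority voting (the libsvm convention).
#' Features are used on their native reflectance scale: multiplicative
#' scatter correction already places spectra on a common, comparable scale,
#' and the tuning box for the kernel width `g` is calibrated to raw
#' reflectance distances.
#'
#' @param x A spectra set or feature matrix.
#' @param y Class labels (taken from `x` when it is a spectra set).
#' @param params An [svm_params()].
#' @return A `trained_classifier` (family `"svm"`).
#' @export
svm_train <- function(x, y = NULL, params) {
  stopifnot(inherits(params, "svm_params"))
  d <- resolve_xy_matrix(x, y)
  if (nlevels(d$y) < 2) abort("at least 2 classes are required.")
  fit <- e1071::svm(d$X, d$y, kernel = "radial", cost = params$c,
                    gamma = params$g, scale = FALSE)
  structure(list(family = "svm", fit = fit, params = params,
                 classes = levels(d$y), n_features = ncol(d$X)),
            class = "trained_classifier")
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("expected %d features, got %d.", object$n_features, ncol(X)))
  }
  if (object$family == "svm") {
    factor(as.character(predict(object$fit, X)), levels = object$classes)
  } else {
    colnames(X) <- object$pf$colnames
    pred <- pls_predict_classes(object$pf, X)[[object$ncomp]]
    factor(pred, levels = object$classes)
  }
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("# %s classifier on %d features, classes: %s\n",
              toupper(x$family), x$n_features, paste(x$classes, collapse = ", ")))
  invisible(x)
}

make_cv_folds <- function(y, folds, seed) {
  tab <- table(y)
  small <- names(tab)[tab < folds]
  if (length(small) > 0) {
    abort(sprintf("class %s has fewer members than the %d folds.",
                  paste(small, collapse = ", "), folds))
  }
  stratified_folds(y, folds, seed)
}

#' Cross-validated SVM accuracy (the tuning fitness)
#'
#' Mean held-out accuracy of an RBF-SVM over a seeded stratified k-fold
#' split. With a fixed seed (or an explicit `fold_ids` assignment) repeat calls return
#' identical values, which the optimizers require.
#'
#' @inheritParams svm_train
#' @param folds Number of folds; every class must have at least that many
#'   members.
#' @param seed Integer seed for the fold assignment.
#' @param fold_ids Optional precomputed fold assignment (overrides `seed`);
#'   used to share folds across all evaluations of one tuning run.
#' @return Accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(x, y = NULL, params, folds = 5, seed = 1L,
                       fold_ids = NULL) {
  stopifnot(inherits(params, "svm_params"))
  d <- resolve_xy_matrix(x, y)
  fold <- fold_ids %||% make_cv_folds(d$y, folds, seed)
  accs <- numeric(max(fold))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    fit <- e1071::svm(d$X[tr, , drop = FALSE], d$y[tr], kernel = "radial",
                      cost = params$c, gamma = params$g, scale = FALSE)
    accs[f] <- mean(as.character(predict(fit, d$X[!tr, , drop = FALSE])) ==
                      as.character(d$y[!tr]))
  }
  mean(accs)
}

#' Tune SVM parameters with a metaheuristic optimizer
#'
#' Runs the chosen optimizer over the two-dimensional `(c, g)` box
#' `[2^-2, 2^8]^2`, maximizing [cv_fitness()] (internally minimizing
#' `1 - accuracy`). The stratified folds are built once per tuning run and
#' shared across every fitness evaluation, so optimizer comparisons on the
#' same seed are paired.
#'
#' @inheritParams svm_train
#' @param optimizer One of `"mrsa"`, `"rsa"`, `"ga"`, `"pso"`.
#' @param params An [rsa_params()] giving population size, iteration budget
#'   and seed (the GA/PSO baselines reuse its `n_candidates`/`max_iters`).
#' @param folds Cross-validation folds for the fitness.
#' @return A `tune_result` list: `params` (the best [svm_params()]), `result`
#'   (the raw `optimizer_result`), and `accuracy_trace` (best CV accuracy per
#'   iteration, non-decreasing).
#' @export
tune_svm <- function(x, y = NULL, optimizer = c("mrsa", "rsa", "ga", "pso"),
                     params = rsa_params(), folds = 5) {
  optimizer <- match.arg(optimizer)
  d <- resolve_xy_matrix(x, y)
  fold_ids <- make_cv_folds(d$y, folds, derive_seed(params$seed, 11L))
  objective <- function(pos) {
    1 - cv_fitness(d$X, d$y, svm_params(pos[1], pos[2]), fold_ids = fold_ids)
  }
  space <- search_space(c(2^-2, 2^-2), c(2^8, 2^8))
  res <- switch(optimizer,
    mrsa = mrsa_minimize(objective, space, params),
    rsa = rsa_minimize(objective, space, params),
    ga = baseline_minimize("ga", objective, space, n = params$n_candidates,
                           iters = params$max_iters, seed = params$seed),
    pso = baseline_minimize("pso", objective, space, n = params$n_candidates,
                            iters = params$max_iters, seed = params$seed)
  )
  structure(list(
    params = svm_params(res$best_position[1], res$best_position[2]),
    result = res,
    accuracy_trace = 1 - res$trace,
    optimizer = optimizer
  ), class = "tune_result")
}

#' Exhaustive grid search over (c, g)
#'
#' Evaluates [cv_fitness()] on every grid point with one shared fold
#' assignment and returns the argmax; ties break toward the smaller `c`,
#' then the smaller `g`.
#'
#' @inheritParams cv_fitness
#' @param c_values,g_values Candidate values.
#' @return The best [svm_params()], with the full grid as attribute `"grid"`.
#' @export
grid_search_cg <- function(x, y = NULL, c_values, g_values, folds = 5,
                           seed = 1L) {
  if (length(c_values) == 0 || length(g_values) == 0) abort("empty grid.")
  d <- resolve_xy_matrix(x, y)
  fold_ids <- make_cv_folds(d$y, folds, derive_seed(seed, 11L))
  grid <- tidyr::expand_grid(c = sort(c_values), g = sort(g_values))
  grid$fitness <- purrr::map2_dbl(grid$c, grid$g, function(ci, gi) {
    cv_fitness(d$X, d$y, svm_params(ci, gi), fold_ids = fold_ids)
  })
  best <- grid[order(-grid$fitness, grid$c, grid$g), ][1, ]
  out <- svm_params(best$c, best$g)
  attr(out, "grid") <- grid
  out
}

#' Train a PLS-DA classifier
#'
#' One-hot response PLS regression with argmax decoding; the latent-variable
#' count in `[1, max_lv]` is chosen by stratified cross-validated accuracy
#' (ties toward fewer components); features enter on their native scale and
#' are centred inside the PLS fit. `max_lv` is capped at the feature rank
#' with a warning.
#'
#' @inheritParams svm_train
#' @param max_lv Maximum latent variables considered.
#' @param folds Cross-validation folds.
#' @param seed Integer seed for the folds.
#' @return A `trained_classifier` (family `"plsda"`) with field `ncomp`.
#' @export
plsda_train <- function(x, y = NULL, max_lv = 15, folds = 5, seed = 1L) {
  d <- resolve_xy_matrix(x, y)
  if (nlevels(d$y) < 2) abort("at least 2 classes are required.")
  Xs <- d$X
  rk <- qr(Xs)$rank
  if (max_lv > rk) {
    warn(sprintf("max_lv = %d exceeds the feature rank %d; capping.", max_lv, rk))
    max_lv <- rk
  }
  max_lv <- max(1, min(max_lv, ncol(Xs), nrow(Xs) - 1))
  fold <- make_cv_folds(d$y, folds, seed)
  correct <- numeric(max_lv)
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    pf <- pls_fit(Xs[tr, , drop = FALSE], d$y[tr], max_lv, levels(d$y))
    preds <- pls_predict_classes(pf, Xs[!tr, , drop = FALSE])
    for (h in seq_len(max_lv)) {
      hh <- min(h, pf$ncomp)
      correct[h] <- correct[h] + sum(preds[[hh]] == as.character(d$y[!tr]))
    }
  }
  ncomp <- which.max(correct)
  pf <- pls_fit(Xs, d$y, max_lv, levels(d$y))
  structure(list(family = "plsda", pf = pf, ncomp = min(ncomp, pf$ncomp),
                 classes = levels(d$y), n_features = ncol(d$X),
                 cv_correct = correct / nrow(d$X)),
            class = "trained_classifier")
}
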