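#' Exponentially decreasing retention schedule for CARS
#'
#' The fraction of bands retained at Monte Carlo run i is `r_i = a exp(-k i)`
#' with `a` and `k` solved from the boundary conditions that run 1 keeps all
#' `p` bands and the final run keeps 2: `a = (p/2)^(1/(N-1))`,
#' `k = log(p/2)/(N-1)`.
#'
#' @param n_bands Number of bands p.
#' @param runs Number of Monte Carlo runs N.
#' @return A tibble with `run`, `ratio` and `n_keep` (ratio rounded to bands).
#' @export
#' @examples
#' edf_schedule(934, 50)
edf_schedule <- function(n_bands, runs) {
  stopifnot(n_bands >= 2, runs >= 2)
  a <- (n_bands / 2)^(1 / (runs - 1))
  k <- log(n_bands / 2) / (runs - 1)
  run <- seq_len(runs)
  ratio <- a * exp(-k * run)
  tibble(run = run, ratio = ratio,
         n_keep = pmax(2, round_half_up(ratio * n_bands)))
}

new_selection_result <- function(indices, wavelengths, diagnostics, method) {
  structure(
    list(
      selected_indices = sort(unique(as.integer(indices))),
      selected_wavelengths = if (is.null(wavelengths)) NULL else
        sort(wavelengths[sort(unique(as.integer(indices)))]),
      diagnostics = diagnostics,
      method = method
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("# %s selection: %d bands\n", toupper(x$method),
              length(x$selected_indices)))
  if (!is.null(x$selected_wavelengths)) {
    cat("# wavelengths (nm):",
        paste(sprintf("%.1f", head(x$selected_wavelengths, 12)), collapse = " "),
        if (length(x$selected_wavelengths) > 12) "..." else "", "\n")
  }
  invisible(x)
}

resolve_xy <- function(x, y) {
  if (is.data.frame(x)) {
    list(X = spectra_matrix(x), y = spectra_labels(x), wl = wavelengths(x))
  } else {
    if (is.null(y)) abort("`y` is required when `x` is a matrix.")
    list(X = as.matrix(x), y = factor(y), wl = NULL)
  }
}

# stratified fold assignment used across the variable-selection scorers
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(as.character(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# CV misclassification rate of a PLS-DA (argmax) model on X[, idx]; the
# component count with the lowest error within the same CV pass is used.
cars_cv_error <- function(X, y, idx, fold, max_comp = 10) {
  folds <- max(fold)
  ncomp <- max(1, min(max_comp, length(idx) - 1))
  classes <- sort(unique(as.character(y)))
  err <- matrix(0, folds, ncomp)
  for (f in seq_len(folds)) {
    tr <- fold != f
    pf <- pls_fit(X[tr, idx, drop = FALSE], y[tr], ncomp, classes)
    preds <- pls_predict_classes(pf, X[!tr, idx, drop = FALSE])
    for (h in seq_along(preds)) {
      err[f, h] <- mean(preds[[h]] != as.character(y[!tr]))
    }
    if (pf$ncomp < ncomp) err[f, (pf$ncomp + 1):ncomp] <- err[f, pf$ncomp]
  }
  min(colMeans(err))
}

#' CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling for classification. Each Monte
#' Carlo run fits a PLS model (one-hot class encoding) on a random 80%
#' calibration subset restricted to the currently retained bands, weights
#' every band by its absolute regression coefficient, enforces the
#' exponentially decreasing retention count ([edf_schedule()]) by keeping the
#' top-weighted bands, and then applies adaptive reweighted sampling
#' (weighted sampling with replacement, weight proportional to the
#' coefficient magnitude). Each run's retained subset is scored by
#' cross-validated misclassification of a PLS-DA model; the subset with the
#' minimal CV error wins, ties broken toward the smaller subset.
#'
#' @param x A spectra set, or a numeric feature matrix.
#' @param y Class labels (ignored when `x` is a spectra set).
#' @param runs Number of Monte Carlo sampling runs.
#' @param folds Cross-validation folds for subset scoring.
#' @param seed Integer seed.
#' @param calib_fraction Fraction of samples drawn as the per-run
#'   calibration subset.
#' @param max_comp Cap on PLS components.
#' @return A `selection_result` with selected band indices (1-based into the
#'   supplied band axis), their wavelengths when known, and per-run
#'   diagnostics (`run`, `n_retained`, `cv_error`).
#' @export
cars_select <- function(x, y = NULL, runs = 50, folds = 5, seed = 1L,
                        calib_fraction = 0.8, max_comp = 10) {
  dat <- resolve_xy(x, y)
  X <- dat$X; yy <- droplevels(factor(dat$y))
  p <- ncol(X); n <- nrow(X)
  if (nlevels(yy) < 2) abort("CARS needs at least 2 classes.")
  if (runs < 2) abort("`runs` must be >= 2.")
  if (p < 2) abort("need at least 2 bands.")
  sched <- edf_schedule(p, runs)
  fold <- stratified_folds(yy, folds, derive_seed(seed, 97L))
  set.seed(as.integer(seed))
  retained <- seq_len(p)
  subsets <- vector("list", runs)
  sizes <- integer(runs); errs <- numeric(runs)
  classes <- sort(unique(as.character(yy)))
  for (i in seq_len(runs)) {
    cal <- sort(sample.int(n, max(2, round(calib_fraction * n))))
    ncomp <- max(1, min(max_comp, length(retained) - 1))
    pf <- pls_fit(X[cal, retained, drop = FALSE], yy[cal], ncomp, classes)
    w <- pls_band_weights(pf)
    if (all(w == 0) || !all(is.finite(w))) {
      warn("degenerate PLS fit (all coefficients zero); using uniform weights.")
      w <- rep(1, length(retained))
    }
    keep_n <- min(sched$n_keep[i], length(retained))
    edf_set <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
    w_edf <- w[match(edf_set, retained)]
    if (all(w_edf == 0)) w_edf <- rep(1, length(w_edf))
    ars <- sample(edf_set, size = keep_n, replace = TRUE, prob = w_edf)
    retained <- sort(unique(ars))
    if (length(retained) < 2) retained <- sort(unique(c(retained, edf_set)))[1:2]
    subsets[[i]] <- retained
    sizes[i] <- length(retained)
    errs[i] <- cars_cv_error(X, yy, retained, fold, max_comp)
  }
  best <- order(errs, sizes)[1]
  diagnostics <- tibble(run = seq_len(runs), n_retained = sizes, cv_error = errs)
  new_selection_result(subsets[[best]], dat$wl, diagnostics, "cars")
}

#' SPA forward chain from a given start column
#'
#' Successive projections: starting from column `start`, repeatedly add the
#' column whose projection onto the orthogonal complement of the selected
#' ones has the largest norm. A duplicated column has zero residual norm and
#' is never selected twice.
#'
#' @param X Feature matrix.
#' @param start Index of the first selected column.
#' @param n_max Chain length.
#' @return Integer vector of column indices, length `n_max`.
#' @export
spa_chain <- function(X, start, n_max) {
  X <- as.matrix(X)
  p <- ncol(X)
  chain <- integer(n_max)
  chain[1] <- start
  R <- X
  for (step in seq_len(n_max - 1)) {
    v <- R[, chain[step]]
    nv <- sum(v^2)
    if (nv > 0) {
      proj <- as.numeric(crossprod(v, R)) / nv
      R <- R - v %o% proj
    }
    norms <- colSums(R^2)
    norms[chain[seq_len(step)]] <- -Inf
    chain[step + 1] <- which.max(norms)
  }
  chain
}

# CV misclassification of a linear least-squares one-hot classifier (fast
# screening scorer)
ls_cv_error <- function(X, y, fold) {
  classes <- sort(unique(as.character(y)))
  Y <- one_hot(y, classes)
  wrong <- 0
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    A <- cbind(1, X[tr, , drop = FALSE])
    B <- qr.coef(qr(A), Y[tr, , drop = FALSE])
    B[is.na(B)] <- 0
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% B
    wrong <- wrong + sum(classes[max.col(pred, ties.method = "first")] !=
                           as.character(y[!tr]))
  }
  wrong / length(y)
}

# CV misclassification of an RBF-SVM with library-default parameters
svm_cv_error <- function(X, y, fold) {
  wrong <- 0
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]), kernel = "radial",
                      scale = FALSE)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(y[!tr]))
  }
  wrong / length(y)
}

#' SPA wavelength selection
#'
#' Successive projections algorithm: forward chains of minimally collinear
#' bands are grown from a set of candidate start columns ([spa_chain()]).
#' For every cardinality in `[n_min, n_max]` the chain prefixes are screened
#' by cross-validated error of a fast linear (one-hot least-squares)
#' classifier; the winning subset per cardinality is then scored by
#' cross-validated error of the downstream RBF-SVM, and the best
#' (cardinality, chain) pair is returned, ties broken toward fewer bands.
#'
#' @inheritParams cars_select
#' @param n_min,n_max Cardinality range to consider.
#' @param n_starts Number of candidate start columns (the largest-norm
#'   columns); defaults to `min(30, p)`.
#' @return A `selection_result`; diagnostics hold per-cardinality CV error.
#' @export
spa_select <- function(x, y = NULL, n_min = 5, n_max = 20, folds = 5,
                       seed = 1L, n_starts = NULL) {
  dat <- resolve_xy(x, y)
  X <- dat$X; yy <- droplevels(factor(dat$y))
  p <- ncol(X)
  if (n_max > p) abort("`n_max` cannot exceed the number of bands.")
  if (n_min < 1) abort("`n_min` must be >= 1.")
  if (qr(X)$rank < n_min) {
    abort("X has fewer independent columns than `n_min`.")
  }
  n_starts <- n_starts %||% min(30L, p)
  fold <- stratified_folds(yy, folds, derive_seed(seed, 89L))
  starts <- order(colSums(X^2), decreasing = TRUE)[seq_len(n_starts)]
  chains <- lapply(starts, function(s) spa_chain(X, s, n_max))
  cards <- n_min:n_max
  winner <- vector("list", length(cards))
  final_err <- numeric(length(cards))
  for (ci in seq_along(cards)) {
    L <- cards[ci]
    screen <- vapply(chains, function(ch) ls_cv_error(X[, ch[1:L], drop = FALSE],
                                                      yy, fold), numeric(1))
    winner[[ci]] <- chains[[which.min(screen)]][1:L]
    final_err[ci] <- svm_cv_error(X[, winner[[ci]], drop = FALSE], yy, fold)
  }
  best <- order(final_err, cards)[1]
  diagnostics <- tibble(n_bands = cards, cv_error = final_err)
  new_selection_result(winner[[best]], dat$wl, diagnostics, "spa")
}
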