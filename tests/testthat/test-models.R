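test_that("RBF-SVM separates well-spaced blobs perfectly", {
  d <- blob_data(1)
  fit <- svm_train(d$X, d$y, svm_params(10, 1))
  expect_equal(mean(predict(fit, d$X) == d$y), 1)
  expect_true(all(levels(predict(fit, d$X)) %in% c("A", "B")))
  expect_error(svm_train(d$X, rep("A", 100), svm_params(10, 1)), "2 classes")
  expect_error(svm_params(0.1, 1), "lie in")
  expect_error(svm_params(1, 512), "lie in")
})

test_that("cv_fitness is a deterministic accuracy in [0, 1]", {
  d <- msc_train_test(1)$train
  X <- spectra_matrix(d); y <- spectra_labels(d)
  f1 <- cv_fitness(X, y, svm_params(10, 16), folds = 5, seed = 3)
  f2 <- cv_fitness(X, y, svm_params(10, 16), folds = 5, seed = 3)
  expect_identical(f1, f2)
  expect_gte(f1, 0); expect_lte(f1, 1)
  # separable blobs reach exactly 1
  b <- blob_data(2)
  expect_equal(cv_fitness(b$X, b$y, svm_params(10, 1), seed = 1), 1)
  # a class smaller than the fold count is refused by name
  expect_error(cv_fitness(X[1:20, ], factor(rep(c("NM", "SH"), c(17, 3))),
                          svm_params(10, 1), folds = 5), "SH")
})

test_that("cv_fitness is invariant to feature-column permutation", {
  d <- msc_train_test(2)$train
  X <- spectra_matrix(d); y <- spectra_labels(d)
  perm <- sample(ncol(X))
  f1 <- cv_fitness(X, y, svm_params(10, 16), folds = 5, seed = 4)
  f2 <- cv_fitness(X[, perm], y, svm_params(10, 16), folds = 5, seed = 4)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("tuning returns in-box parameters with a non-decreasing accuracy trace", {
  d <- msc_train_test(3)$train
  tn <- tune_svm(d, optimizer = "mrsa",
                 params = rsa_params(n_candidates = 5, max_iters = 6, seed = 2),
                 folds = 3)
  expect_gte(tn$params$c, 0.25); expect_lte(tn$params$c, 256)
  expect_gte(tn$params$g, 0.25); expect_lte(tn$params$g, 256)
  expect_true(all(diff(tn$accuracy_trace) >= 0))
  # tuned fitness at least matches the box-centre parameters on shared folds
  X <- spectra_matrix(d); y <- spectra_labels(d)
  fold_ids <- specdefect:::make_cv_folds(y, 3, specdefect:::derive_seed(2, 11L))
  centre <- cv_fitness(X, y, svm_params(2^3, 2^3), fold_ids = fold_ids)
  expect_gte(1 - tn$result$best_fitness, centre)
})

test_that("a 1-candidate, minimal-budget tuner equals its single evaluation", {
  d <- msc_train_test(4)$train
  X <- spectra_matrix(d); y <- spectra_labels(d)
  tn <- tune_svm(X, y, optimizer = "rsa",
                 params = rsa_params(n_candidates = 2, max_iters = 4, seed = 5),
                 folds = 3)
  fold_ids <- specdefect:::make_cv_folds(y, 3, specdefect:::derive_seed(5, 11L))
  direct <- cv_fitness(X, y, tn$params, fold_ids = fold_ids)
  expect_equal(1 - tn$result$best_fitness, direct, tolerance = 1e-12)
})

test_that("grid search equals brute-force enumeration with parsimony ties", {
  d <- msc_train_test(5)$train
  X <- spectra_matrix(d); y <- spectra_labels(d)
  cs <- c(1, 8, 64); gs <- c(0.5, 4, 32)
  best <- grid_search_cg(X, y, cs, gs, folds = 3, seed = 6)
  fold_ids <- specdefect:::make_cv_folds(y, 3, specdefect:::derive_seed(6, 11L))
  grid <- expand.grid(c = cs, g = gs)
  fits <- mapply(function(ci, gi) cv_fitness(X, y, svm_params(ci, gi),
                                             fold_ids = fold_ids),
                 grid$c, grid$g)
  expect_equal(max(fits), attr(best, "grid")$fitness[
    attr(best, "grid")$c == best$c & attr(best, "grid")$g == best$g])
  winners <- grid[fits == max(fits), ]
  winners <- winners[order(winners$c, winners$g), ]
  expect_equal(best$c, winners$c[1])
  expect_equal(best$g, winners$g[1])
  one <- grid_search_cg(X, y, 8, 2, folds = 3, seed = 1)
  expect_equal(c(one$c, one$g), c(8, 2))
})

test_that("PLS-DA separates orthogonal class means and caps latent variables", {
  set.seed(8)
  n <- 30
  X <- rbind(
    cbind(rnorm(n, 3), rnorm(n, 0), matrix(rnorm(3 * n, sd = 0.5), n)),
    cbind(rnorm(n, 0), rnorm(n, 3), matrix(rnorm(3 * n, sd = 0.5), n))
  )
  y <- rep(c("A", "B"), each = n)
  fit <- plsda_train(X, y, max_lv = 2, folds = 5, seed = 1)
  expect_equal(mean(predict(fit, X) == y), 1)
  expect_lte(fit$ncomp, 2)
  # rank cap warns
  Xlow <- X[, 1:2] %*% matrix(runif(10), 2, 5)
  expect_warning(plsda_train(Xlow, y, max_lv = 5, folds = 5, seed = 1), "rank")
  a <- plsda_train(X, y, max_lv = 2, folds = 5, seed = 2)
  b <- plsda_train(X, y, max_lv = 2, folds = 5, seed = 2)
  expect_identical(predict(a, X), predict(b, X))
})
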