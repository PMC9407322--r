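balanced_counts <- function(x) as.integer(table(spectra_labels(x)))

test_that("all four methods balance every class to the majority count", {
  d <- msc_train_test(1)$train  # counts 28/42/14
  for (meth in c("ros", "smote", "blsmote", "adasyn")) {
    out <- suppressWarnings(oversample(d, meth, seed = 3))
    expect_equal(balanced_counts(out), rep(42L, 3), info = meth)
    # original rows untouched, labels preserved
    expect_equal(spectra_matrix(out)[seq_len(nrow(d)), ], spectra_matrix(d),
                 info = meth)
    expect_equal(as.character(spectra_labels(out))[seq_len(nrow(d))],
                 as.character(spectra_labels(d)), info = meth)
  }
  # already-balanced input returned unchanged
  bal <- suppressWarnings(oversample(d, "ros", seed = 1))
  expect_identical(suppressWarnings(random_oversample(bal, seed = 2)), bal)
})

test_that("random oversampling only copies existing rows", {
  d <- msc_train_test(2)$train
  out <- random_oversample(d, seed = 5)
  X <- spectra_matrix(d)
  synth <- spectra_matrix(out)[-seq_len(nrow(d)), , drop = FALSE]
  lab_new <- spectra_labels(out)[-seq_len(nrow(d))]
  for (i in seq_len(nrow(synth))) {
    hits <- which(apply(X, 1, function(r) isTRUE(all.equal(r, synth[i, ],
                                                           tolerance = 0))))
    expect_gt(length(hits), 0)
    expect_true(as.character(lab_new[i]) %in%
                  as.character(spectra_labels(d)[hits]))
  }
})

test_that("SMOTE synthetics lie on segments between same-class points", {
  d <- msc_train_test(3)$train
  out <- smote(d, k = 5, seed = 7)
  X <- spectra_matrix(d)
  lab <- as.character(spectra_labels(d))
  synth <- spectra_matrix(out)[-seq_len(nrow(d)), , drop = FALSE]
  lab_new <- as.character(spectra_labels(out))[-seq_len(nrow(d))]
  set.seed(1)
  for (i in sample(nrow(synth), 10)) {
    cls_rows <- X[lab == lab_new[i], , drop = FALSE]
    # exhaustive pair search: some same-class pair (p, q) must carry the
    # point on its segment, synth = p + lambda (q - p), lambda in [0, 1)
    pairs <- utils::combn(nrow(cls_rows), 2)
    resid <- apply(pairs, 2, function(pq) {
      p <- cls_rows[pq[1], ]; q <- cls_rows[pq[2], ]
      v <- q - p
      lam <- sum((synth[i, ] - p) * v) / sum(v^2)
      if (lam < -1e-9 || lam > 1 + 1e-9) return(Inf)
      sqrt(sum((p + lam * v - synth[i, ])^2))
    })
    expect_lt(min(resid), 1e-9)
  }
})

test_that("a 2-point identical minority class synthesizes copies of itself", {
  X <- rbind(matrix(seq(0.3, 0.7, length.out = 40), 10, 4, byrow = TRUE) +
               matrix(stats::runif(40, 0, 0.01), 10, 4),
             matrix(0.5, 2, 4))
  s <- spectra_set(X, c(500, 600, 700, 800),
                   c(rep("SH", 10), rep("MD", 2)))
  out <- suppressWarnings(smote(s, k = 5, seed = 1))
  synth <- spectra_matrix(out)[-seq_len(12), , drop = FALSE]
  md_synth <- synth[as.character(spectra_labels(out))[-seq_len(12)] == "MD", ,
                    drop = FALSE]
  expect_true(all(abs(md_synth - 0.5) < 1e-12))
  expect_error(smote(spectra_set(X[1:11, ], c(500, 600, 700, 800),
                                 c(rep("SH", 10), "MD"))), ">= 2")
})

test_that("borderline categories match a brute-force neighbour count", {
  # 2-D toy: a minority point deep in majority territory (noise), one at the
  # boundary (danger), one inside its own cluster (safe)
  maj <- cbind(runif(30, 0, 1), runif(30, 0, 1))
  min_pts <- rbind(c(0.5, 0.5),    # surrounded by majority -> noise
                   c(1.45, 0.5),   # boundary -> mixed neighbours
                   c(2.5, 0.5))    # deep in minority cluster -> safe
  min_cluster <- cbind(runif(20, 2.2, 2.8), runif(20, 0.2, 0.8))
  X <- rbind(maj, min_pts, min_cluster)
  labels <- c(rep("SH", 30), rep("MD", 23))
  set.seed(99)
  cats <- borderline_categories(X, labels, "MD", m = 5)
  # independent brute-force oracle
  oracle <- sapply(which(labels == "MD"), function(i) {
    d <- sqrt(colSums((t(X) - X[i, ])^2)); d[i] <- Inf
    nn <- order(d)[1:5]
    n_other <- sum(labels[nn] != "MD")
    if (n_other == 5) "noise" else if (n_other >= 2.5) "danger" else "safe"
  })
  expect_equal(cats$category, unname(oracle))
  expect_equal(cats$category[1], "noise")
  expect_equal(cats$category[3], "safe")
})

test_that("borderline-SMOTE falls back to plain SMOTE when nothing is in danger", {
  # fully separated classes: every minority point is safe
  set.seed(4)
  X <- rbind(matrix(runif(60, 0, 0.2), 15, 4),
             matrix(runif(60, 0.8, 1.0), 15, 4),
             matrix(runif(24, 0.45, 0.55), 6, 4))
  s <- spectra_set(X, c(500, 600, 700, 800),
                   rep(c("NM", "SH", "MD"), c(15, 15, 6)))
  expect_warning(out <- borderline_smote(s, seed = 2), "danger")
  expect_equal(balanced_counts(out), rep(15L, 3))
})

test_that("ADASYN weights normalize and drive quotas by difficulty", {
  d <- msc_train_test(4)$train
  X <- spectra_matrix(d)
  lab <- as.character(spectra_labels(d))
  set.seed(1)
  w <- adasyn_weights(X, lab, "MD", k = 5)
  expect_equal(sum(w$r_hat), 1, tolerance = 1e-12)
  expect_true(all(w$r >= 0 & w$r <= 1))
  # a sample with no cross-class neighbours gets no quota while others do
  if (any(w$r == 0) && any(w$r > 0)) {
    need <- sum(lab == "SH") - sum(lab == "MD")
    quota <- specdefect:::round_half_up(w$r_hat * need)
    expect_true(all(quota[w$r == 0] == 0))
  }
  out <- suppressWarnings(adasyn(d, seed = 8))
  expect_equal(balanced_counts(out), rep(max(table(lab)), 3))
})

test_that("oversampling is reproducible and within the class convex hull", {
  d <- msc_train_test(5)$train
  for (meth in c("ros", "smote", "blsmote", "adasyn")) {
    a <- suppressWarnings(oversample(d, meth, seed = 11))
    b <- suppressWarnings(oversample(d, meth, seed = 11))
    expect_identical(a, b, info = meth)
  }
  out <- smote(d, seed = 11)
  X <- spectra_matrix(d); lab <- as.character(spectra_labels(d))
  synth <- spectra_matrix(out)[-seq_len(nrow(d)), , drop = FALSE]
  lab_new <- as.character(spectra_labels(out))[-seq_len(nrow(d))]
  # segment property implies staying within per-coordinate class ranges
  for (cl in unique(lab_new)) {
    rng_lo <- apply(X[lab == cl, , drop = FALSE], 2, min)
    rng_hi <- apply(X[lab == cl, , drop = FALSE], 2, max)
    ss <- synth[lab_new == cl, , drop = FALSE]
    expect_true(all(t(ss) >= rng_lo - 1e-12) && all(t(ss) <= rng_hi + 1e-12),
                info = cl)
  }
})
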