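test_that("generator returns the requested geometry and class structure", {
  s <- generate_spectra(sim_config())
  expect_equal(dim(spectra_matrix(s)), c(600, 934))
  expect_equal(as.integer(table(spectra_labels(s))), c(200, 302, 98))
  wl <- wavelengths(s)
  expect_equal(range(wl), c(400, 1100))
  expect_true(all(diff(wl) > 0))
  m <- spectra_matrix(s)
  expect_true(all(m > 0 & m <= 1.2))

  lab <- spectra_labels(s)
  mu <- sapply(c("NM", "SH", "MD"), function(cl) colMeans(m[lab == cl, ]))
  # class-ordered mean reflectance in the NIR plateau
  nir <- wl >= 700
  expect_true(all(mu[nir, "NM"] > mu[nir, "SH"]))
  expect_true(all(mu[nir, "SH"] > mu[nir, "MD"]))
  # low visible reflectance, sharp red-edge rise
  expect_true(all(mu[wl <= 600, ] < 0.35))
  rise <- mu[which.min(abs(wl - 750)), ] - mu[which.min(abs(wl - 600)), ]
  expect_true(all(rise > 0.2))
  # local minima near the 890 and 990 nm absorption dips
  for (ctr in c(890, 990)) {
    reg <- which(abs(wl - ctr) < 25)
    dip_at <- wl[reg[which.min(mu[reg, "NM"])]]
    expect_lt(abs(dip_at - ctr), 15)
  }
})

test_that("mildewed class has the largest spectral dispersion", {
  s <- generate_spectra(sim_config(seed = 7))
  m <- spectra_matrix(s)
  lab <- spectra_labels(s)
  sds <- sapply(c("NM", "SH", "MD"), function(cl) mean(apply(m[lab == cl, ], 2, sd)))
  expect_true(sds[["MD"]] > sds[["NM"]])
  expect_true(sds[["MD"]] > sds[["SH"]])
})

test_that("degenerate and invalid generator configs behave as specified", {
  one <- generate_spectra(sim_config(class_counts = c(1, 0, 0), n_bands = 10))
  expect_equal(nrow(one), 1)
  expect_equal(as.character(spectra_labels(one)), "NM")
  expect_error(generate_spectra(sim_config(class_counts = c(0, 0, 0))), "zero")
  expect_error(generate_spectra(sim_config(n_bands = 3)), "at least 4")
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_spectra(sim_config(class_counts = c(10, 15, 5), n_bands = 20,
                                   seed = 42))
  b <- generate_spectra(sim_config(class_counts = c(10, 15, 5), n_bands = 20,
                                   seed = 42))
  expect_identical(a, b)
})

test_that("a linear classifier separates NM from MD on raw spectra", {
  s <- generate_spectra(sim_config(seed = 11))
  m <- spectra_matrix(s); lab <- spectra_labels(s)
  sub <- lab %in% c("NM", "MD")
  X <- m[sub, ]; y <- droplevels(lab[sub])
  fold <- specdefect:::stratified_folds(y, 5, 1)
  acc <- mean(sapply(1:5, function(f) {
    fit <- e1071::svm(X[fold != f, ], y[fold != f], kernel = "linear",
                      scale = FALSE)
    mean(predict(fit, X[fold == f, ]) == y[fold == f])
  }))
  expect_gte(acc, 0.9)
})

test_that("stratified split reproduces the 7:3 class partition", {
  s <- generate_spectra(sim_config(seed = 2))
  sp <- stratified_split(s, 0.7, seed = 9)
  expect_equal(as.integer(table(spectra_labels(sp$train))), c(140, 211, 69))
  expect_equal(as.integer(table(spectra_labels(sp$test))), c(60, 91, 29))
})

test_that("split is a seeded disjoint partition with rounding edge cases", {
  s <- small_spectra(3, counts = c(10, 12, 3), bands = 12)
  sp <- stratified_split(s, 0.7, seed = 1)
  expect_setequal(c(sp$train$id, sp$test$id), s$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- stratified_split(s, 0.7, seed = 1)
  expect_identical(sp, sp2)
  # near-1 fraction pushes a whole small class into training
  sp3 <- stratified_split(s, 0.999, seed = 1)
  expect_equal(sum(spectra_labels(sp3$train) == "MD"), 3)
  expect_equal(sum(spectra_labels(sp3$test) == "MD"), 0)
  expect_error(stratified_split(s, 1.2), "0, 1")
})

test_that("spectra CSV round-trips exactly enough for analysis", {
  s <- small_spectra(5, counts = c(4, 5, 3), bands = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  r <- read_spectra_csv(path)
  expect_equal(wavelengths(r), wavelengths(s))
  expect_equal(r$id, s$id)
  expect_equal(spectra_matrix(r), spectra_matrix(s), tolerance = 1e-12)
})

test_that("spectra_set validates its invariants", {
  expect_error(spectra_set(matrix(0.5, 2, 3), c(1, 2), c("NM", "SH")), "column")
  expect_error(spectra_set(matrix(0.5, 2, 2), c(2, 1), c("NM", "SH")), "increasing")
  expect_error(spectra_set(matrix(0.5, 2, 2), c(1, 2), c("NM", "XX")), "labels")
  expect_error(spectra_set(matrix(0.5, 2, 2), c(1, 2), c("NM", "SH"),
                           ids = c("a", "a")), "unique")
})
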