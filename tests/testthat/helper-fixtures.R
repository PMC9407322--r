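# Small fixtures shared across test files; everything is generated in code.

small_spectra <- function(seed = 1, counts = c(40, 60, 20), bands = 40) {
  generate_spectra(sim_config(class_counts = counts, n_bands = bands,
                              seed = seed))
}

msc_train_test <- function(seed = 1, counts = c(40, 60, 20), bands = 40) {
  s <- small_spectra(seed, counts, bands)
  sp <- stratified_split(s, 0.7, seed = seed + 50)
  ref <- msc_fit(sp$train)
  list(train = msc_apply(sp$train, ref), test = msc_apply(sp$test, ref),
       ref = ref)
}

# two well-separated Gaussian blobs in 2-D
blob_data <- function(seed = 1, n = 50, gap = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, mean = gap), n))
  list(X = X, y = rep(c("A", "B"), each = n))
}

# classification task whose signal sits in 3 known columns among iid
# Gaussian distractors
informative_band_data <- function(seed, n = 120, p = 30,
                                  informative = c(3, 10, 20),
                                  collinear = FALSE) {
  set.seed(seed + 1000)
  if (collinear) {
    f <- rnorm(n)
    X <- matrix(f, n, p) + matrix(rnorm(n * p, sd = 0.2), n, p)
    X[, informative] <- matrix(rnorm(n * length(informative)), n)
  } else {
    X <- matrix(rnorm(n * p), n, p)
  }
  lin <- X[, informative[1]] + X[, informative[2]] - X[, informative[3]]
  y <- ifelse(lin + rnorm(n, sd = 0.3) > 0, "A", "B")
  list(X = X, y = y, informative = informative)
}

sphere_fn <- function(x) sum(x^2)
sphere_space <- function() search_space(c(-10, -10), c(10, 10))

# the three-class test confusion with all NM and SH correct and 5 MD errors
# (1 to NM, 4 to SH)
reference_cm <- function() {
  confusion(
    y_true = rep(c("NM", "SH", "MD"), c(60, 91, 29)),
    y_pred = c(rep("NM", 60), rep("SH", 91),
               rep("NM", 1), rep("SH", 4), rep("MD", 24))
  )
}
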