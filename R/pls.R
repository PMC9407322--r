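# Thin wrappers around mixOmics::pls for classification use: the class label
# is encoded as a one-hot indicator matrix, fitted by multi-response PLS
# regression, and decoded by argmax of the predicted responses.

one_hot <- function(y, classes = NULL) {
  y <- as.character(y)
  classes <- classes %||% sort(unique(y))
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

slab <- function(arr, h) {
  # arr is n x q x ncomp; return the n x q slice at component h
  matrix(arr[, , h], nrow = dim(arr)[1], ncol = dim(arr)[2])
}

pls_fit <- function(X, y, ncomp, classes = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  classes <- classes %||% sort(unique(as.character(y)))
  Y <- one_hot(y, classes)
  ncomp <- max(1, min(ncomp, ncol(X), nrow(X) - 1))
  fit <- mixOmics::pls(X, Y, ncomp = ncomp, mode = "regression", scale = FALSE)
  list(fit = fit, classes = classes, ncomp = ncomp, colnames = colnames(X), X = X)
}

# band weights: summed |regression coefficient| across one-hot responses,
# at the largest fitted component count
pls_band_weights <- function(pf) {
  pr <- predict(pf$fit, pf$X[seq_len(min(2, nrow(pf$X))), , drop = FALSE])
  B <- matrix(pr$B.hat[, , pf$ncomp],
              nrow = dim(pr$B.hat)[1], ncol = dim(pr$B.hat)[2])
  rowSums(abs(B))
}

# predicted classes for each component count 1..ncomp: list of factors
pls_predict_classes <- function(pf, Xnew) {
  Xnew <- as.matrix(Xnew)
  colnames(Xnew) <- pf$colnames
  pr <- predict(pf$fit, Xnew)$predict
  lapply(seq_len(pf$ncomp), function(h) {
    pf$classes[max.col(slab(pr, h), ties.method = "first")]
  })
}
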