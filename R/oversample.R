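#' Minority-class oversampling for spectral training sets
#'
#' Four standard imbalance-handling strategies, each applied per minority
#' class against the union of the other classes and balancing every class up
#' to the majority-class count: random oversampling (exact copies), SMOTE
#' (linear interpolation between same-class nearest neighbours),
#' borderline-SMOTE (interpolation seeds restricted to "danger" samples near
#' the class boundary) and ADASYN (synthesis quota allocated by local
#' learning difficulty). Distances are Euclidean on the preprocessed feature
#' space and `k = 5` neighbours are used throughout by default. Original
#' rows (including the whole majority class) are never modified; synthetic
#' rows are appended with ids like `SH.s0001`.
#'
#' @param train A spectra set (typically the MSC-corrected training set).
#' @param method One of `"none"`, `"ros"`, `"smote"`, `"blsmote"`, `"adasyn"`.
#' @param k Number of same-class nearest neighbours used for interpolation
#'   (and for ADASYN's all-class difficulty estimate).
#' @param m Number of all-class neighbours for the borderline danger test.
#' @param seed Integer seed; output is byte-reproducible given it.
#' @return A balanced spectra set.
#' @export
oversample <- function(train, method = c("blsmote", "none", "ros", "smote", "adasyn"),
                       k = 5, m = 5, seed = 1L) {
  method <- match.arg(method)
  switch(method,
    none = train,
    ros = random_oversample(train, seed = seed),
    smote = smote(train, k = k, seed = seed),
    blsmote = borderline_smote(train, k = k, m = m, seed = seed),
    adasyn = adasyn(train, k = k, seed = seed)
  )
}

class_counts <- function(labels) table(factor(labels, levels = CLASS_LEVELS))

present_classes <- function(labels) {
  tab <- class_counts(labels)
  names(tab)[tab > 0]
}

# k nearest neighbours of rows `query` among rows `pool` (Euclidean),
# excluding self-matches by row index. Returns an index matrix into `pool`.
knn_index <- function(X, query, pool, k) {
  d2 <- outer(rowSums(X[query, , drop = FALSE]^2),
              rowSums(X[pool, , drop = FALSE]^2), "+") -
    2 * X[query, , drop = FALSE] %*% t(X[pool, , drop = FALSE])
  out <- matrix(NA_integer_, length(query), k)
  for (i in seq_along(query)) {
    d <- d2[i, ]
    d[pool == query[i]] <- Inf
    ord <- order(d)
    out[i, ] <- pool[ord[seq_len(min(k, sum(is.finite(d))))]]
  }
  out
}

append_synthetic <- function(train, synth, labels_new) {
  if (length(labels_new) == 0) return(train)
  wl <- wavelengths(train)
  m <- spectra_matrix(train)
  ids_new <- sprintf("%s.s%04d", labels_new, seq_along(labels_new))
  spectra_set(rbind(m, synth), wl,
              c(as.character(spectra_labels(train)), labels_new),
              c(train$id, ids_new))
}

#' @rdname oversample
#' @export
random_oversample <- function(train, seed = 1L) {
  labels <- spectra_labels(train)
  tab <- class_counts(labels)
  maj <- max(tab)
  set.seed(as.integer(seed))
  X <- spectra_matrix(train)
  synth <- NULL; lab_new <- character(0)
  for (cls in present_classes(labels)) {
    need <- maj - tab[[cls]]
    if (need == 0) next
    idx <- which(labels == cls)
    if (length(idx) == 0) abort(sprintf("class %s is empty.", cls))
    pick <- idx[sample.int(length(idx), need, replace = TRUE)]
    synth <- rbind(synth, X[pick, , drop = FALSE])
    lab_new <- c(lab_new, rep(cls, need))
  }
  append_synthetic(train, synth, lab_new)
}

# Interpolate `need` synthetic points for class `cls`: seeds drawn from
# `seed_idx`, partner drawn among the k same-class nearest neighbours of the
# seed, lambda ~ U[0, 1).
interpolate_class <- function(X, labels, cls, seed_idx, need, k) {
  cls_idx <- which(labels == cls)
  if (length(cls_idx) < 2) {
    abort(sprintf("class %s needs >= 2 samples for interpolation.", cls))
  }
  k_eff <- min(k, length(cls_idx) - 1)
  if (k_eff < k) {
    warn(sprintf("class %s has only %d samples; using %d same-class neighbours.",
                 cls, length(cls_idx), k_eff))
  }
  nn <- knn_index(X, seed_idx, cls_idx, k_eff)
  pick <- seed_idx[sample.int(length(seed_idx), need, replace = TRUE)]
  pos_in_seed <- match(pick, seed_idx)
  partner_col <- sample.int(k_eff, need, replace = TRUE)
  partner <- nn[cbind(pos_in_seed, partner_col)]
  lam <- runif(need)
  X[pick, , drop = FALSE] + lam * (X[partner, , drop = FALSE] - X[pick, , drop = FALSE])
}

#' @rdname oversample
#' @export
smote <- function(train, k = 5, seed = 1L) {
  labels <- spectra_labels(train)
  tab <- class_counts(labels)
  maj <- max(tab)
  set.seed(as.integer(seed))
  X <- spectra_matrix(train)
  synth <- NULL; lab_new <- character(0)
  for (cls in present_classes(labels)) {
    need <- maj - tab[[cls]]
    if (need == 0) next
    seeds <- which(labels == cls)
    synth <- rbind(synth, interpolate_class(X, labels, cls, seeds, need, k))
    lab_new <- c(lab_new, rep(cls, need))
  }
  append_synthetic(train, synth, lab_new)
}

#' Classify minority samples as noise / danger / safe
#'
#' For each sample of `cls`, counts how many of its `m` nearest neighbours
#' over all classes belong to a different class (m'). `m' = m` marks noise,
#' `m/2 <= m' < m` danger, otherwise safe — the borderline-SMOTE partition.
#'
#' @param X Feature matrix.
#' @param labels Class labels, one per row of `X`.
#' @param cls Minority class to categorize.
#' @param m Number of all-class neighbours.
#' @return A tibble with `index`, `n_other` and `category`.
#' @export
borderline_categories <- function(X, labels, cls, m = 5) {
  idx <- which(labels == cls)
  nn <- knn_index(X, idx, seq_len(nrow(X)), m)
  n_other <- rowSums(matrix(labels[nn] != cls, nrow = length(idx)))
  category <- dplyr::case_when(
    n_other == m ~ "noise",
    n_other >= m / 2 ~ "danger",
    TRUE ~ "safe"
  )
  tibble(index = idx, n_other = n_other, category = category)
}

#' @rdname oversample
#' @export
borderline_smote <- function(train, k = 5, m = 5, seed = 1L) {
  labels <- spectra_labels(train)
  tab <- class_counts(labels)
  maj <- max(tab)
  set.seed(as.integer(seed))
  X <- spectra_matrix(train)
  labs_chr <- as.character(labels)
  synth <- NULL; lab_new <- character(0)
  for (cls in present_classes(labels)) {
    need <- maj - tab[[cls]]
    if (need == 0) next
    cats <- borderline_categories(X, labs_chr, cls, m)
    seeds <- cats$index[cats$category == "danger"]
    if (length(seeds) == 0) {
      warn(sprintf(
        "no danger samples in class %s; falling back to plain SMOTE seeds.", cls))
      seeds <- cats$index
    }
    synth <- rbind(synth, interpolate_class(X, labels, cls, seeds, need, k))
    lab_new <- c(lab_new, rep(cls, need))
  }
  append_synthetic(train, synth, lab_new)
}

#' ADASYN difficulty weights
#'
#' Per minority sample, the fraction of its `k` all-class nearest neighbours
#' that belong to another class, normalized to sum to one over the class.
#'
#' @inheritParams borderline_categories
#' @param k Number of all-class neighbours.
#' @return A tibble with `index`, `r` (raw ratio) and `r_hat` (normalized).
#' @export
adasyn_weights <- function(X, labels, cls, k = 5) {
  idx <- which(labels == cls)
  nn <- knn_index(X, idx, seq_len(nrow(X)), k)
  r <- rowSums(matrix(labels[nn] != cls, nrow = length(idx))) / k
  if (sum(r) == 0) {
    warn(sprintf("class %s has no cross-class neighbours; using uniform quotas.", cls))
    r_hat <- rep(1 / length(idx), length(idx))
  } else {
    r_hat <- r / sum(r)
  }
  tibble(index = idx, r = r, r_hat = r_hat)
}

#' @rdname oversample
#' @export
adasyn <- function(train, k = 5, seed = 1L) {
  labels <- spectra_labels(train)
  tab <- class_counts(labels)
  maj <- max(tab)
  set.seed(as.integer(seed))
  X <- spectra_matrix(train)
  labs_chr <- as.character(labels)
  synth <- NULL; lab_new <- character(0)
  for (cls in present_classes(labels)) {
    need <- maj - tab[[cls]]
    if (need == 0) next
    w <- adasyn_weights(X, labs_chr, cls, k)
    quota <- round_half_up(w$r_hat * need)
    seeds <- rep(w$index, quota)
    # trim/pad rounding slack so every class balances exactly to the majority
    if (length(seeds) > need) {
      seeds <- seeds[sample.int(length(seeds), need)]
    } else if (length(seeds) < need) {
      extra <- sample(w$index, need - length(seeds), replace = TRUE, prob = w$r_hat)
      seeds <- c(seeds, extra)
    }
    pts <- matrix(NA_real_, need, ncol(X))
    cls_idx <- which(labels == cls)
    k_eff <- min(k, length(cls_idx) - 1)
    if (length(cls_idx) < 2) abort(sprintf("class %s needs >= 2 samples.", cls))
    nn <- knn_index(X, cls_idx, cls_idx, k_eff)
    pos <- match(seeds, cls_idx)
    partner <- nn[cbind(pos, sample.int(k_eff, need, replace = TRUE))]
    lam <- runif(need)
    pts <- X[seeds, , drop = FALSE] +
      lam * (X[partner, , drop = FALSE] - X[seeds, , drop = FALSE])
    synth <- rbind(synth, pts)
    lab_new <- c(lab_new, rep(cls, need))
  }
  append_synthetic(train, synth, lab_new)
}
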