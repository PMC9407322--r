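#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the fixed reporting
#' order (NM, SH, MD) when the labels come from that alphabet, otherwise in
#' factor-level order.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Optional class order; defaults to the levels of
#'   `factor(y_true)` (the NM/SH/MD order for jujube labels).
#' @return A K x K integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) abort("label vectors must match in length.")
  if (is.null(classes)) {
    classes <- if (all(as.character(y_true) %in% CLASS_LEVELS)) {
      intersect(CLASS_LEVELS, unique(c(as.character(y_true), as.character(y_pred))))
    } else {
      levels(factor(y_true))
    }
  }
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))), classes)
  if (length(bad) > 0) {
    abort(paste0("unknown labels: ", paste(bad, collapse = ", ")))
  }
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(truth = classes, prediction = classes)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("# Confusion matrix (rows = truth, columns = prediction)\n")
  print(unclass(x))
  invisible(x)
}

#' Kappa under the pooled one-vs-rest convention
#'
#' Chance-corrected agreement `(p0 - pe)/(1 - pe)` with the observed
#' agreement `p0` equal to the overall accuracy and the chance agreement
#' taken from the pooled one-vs-rest marginals, which for K classes is the
#' constant `pe = (1 + (K - 1)^2) / K^2` (5/9 for K = 3). For K = 3 this
#' reduces to `kappa = (9 p0 - 5) / 4`.
#'
#' @param p0 Overall accuracy in `[0, 1]`.
#' @param n_classes Number of classes K.
#' @return Kappa in `[-pe/(1-pe), 1]`.
#' @export
kappa_paper <- function(p0, n_classes = 3) {
  stopifnot(p0 >= 0, p0 <= 1, n_classes >= 2)
  pe <- (1 + (n_classes - 1)^2) / n_classes^2
  (p0 - pe) / (1 - pe)
}

#' Cohen's kappa from a confusion matrix
#'
#' Standard chance agreement from the row/column marginals:
#' `pe = sum(row_i * col_i) / n^2`.
#'
#' @param cm A [confusion()] matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_cohen <- function(cm) {
  n <- sum(cm)
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (p0 - pe) / (1 - pe)
}

#' Metric report from a confusion matrix
#'
#' Computes overall accuracy, per-class recall (= per-class accuracy),
#' per-class precision and F1 from one-vs-rest marginals, their unweighted
#' (macro) means, and two kappa conventions: [kappa_paper()] (chance
#' agreement from pooled one-vs-rest marginals) and standard Cohen's
#' [kappa_cohen()]. A class that is never predicted has undefined precision;
#' it is reported as 0 with a warning so macro means stay defined. All
#' values are kept at full precision; rounding to two-decimal percentages
#' happens only in printing.
#'
#' @param cm A [confusion()] matrix.
#' @return A `metrics_report` list.
#' @export
report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) && nrow(cm) == ncol(cm)))
  total <- sum(cm)
  if (total < 1) abort("empty confusion matrix.")
  K <- nrow(cm)
  tp <- diag(cm)
  row_s <- rowSums(cm); col_s <- colSums(cm)
  recall <- ifelse(row_s > 0, tp / row_s, 0)
  if (any(col_s == 0)) {
    warn(sprintf("%d class(es) never predicted; their precision is reported as 0.",
                 sum(col_s == 0)))
  }
  precision <- ifelse(col_s > 0, tp / col_s, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  p0 <- sum(tp) / total
  pe_paper <- (1 + (K - 1)^2) / K^2
  structure(list(
    confusion = cm,
    accuracy = p0,
    per_class_recall = recall,
    per_class_precision = precision,
    per_class_f1 = f1,
    macro_recall = mean(recall),
    macro_precision = mean(precision),
    macro_f1 = mean(f1),
    p0 = p0,
    pe_paper = pe_paper,
    kappa_paper = kappa_paper(p0, K),
    kappa_cohen = kappa_cohen(cm)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f", round_half_up(100 * v, 2))
  cat("# Classification metrics (%)\n")
  cat(sprintf("  accuracy        %s\n", pct(x$accuracy)))
  cat(sprintf("  macro recall    %s\n", pct(x$macro_recall)))
  cat(sprintf("  macro precision %s\n", pct(x$macro_precision)))
  cat(sprintf("  macro F1        %s\n", pct(x$macro_f1)))
  cat(sprintf("  kappa (pooled one-vs-rest) %s\n", pct(x$kappa_paper)))
  cat(sprintf("  kappa (Cohen)   %s\n", pct(x$kappa_cohen)))
  invisible(x)
}

#' Overall accuracy from per-class accuracies
#'
#' Converts per-class accuracies back to integer correct counts
#' (`round(acc * size)`, half-up) and pools them: the size-weighted total
#' accuracy used in per-class accounting tables.
#'
#' @param per_class_accuracy Per-class accuracies; percentages when any
#'   value exceeds 1, else proportions.
#' @param class_sizes Positive class sizes.
#' @return Total accuracy on the same scale as the input.
#' @export
total_from_per_class <- function(per_class_accuracy, class_sizes) {
  stopifnot(length(per_class_accuracy) == length(class_sizes),
            all(class_sizes > 0))
  pct <- any(per_class_accuracy > 1)
  acc <- if (pct) per_class_accuracy / 100 else per_class_accuracy
  correct <- round_half_up(acc * class_sizes)
  out <- sum(correct) / sum(class_sizes)
  if (pct) 100 * out else out
}
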