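#' Tidy an optimizer result
#'
#' @param x An `optimizer_result`.
#' @param ... Unused.
#' @return A tibble with `iteration` and `best_fitness`.
#' @export
tidy.optimizer_result <- function(x, ...) {
  tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}

#' @rdname tidy.optimizer_result
#' @export
glance.optimizer_result <- function(x, ...) {
  tibble(method = x$method, best_fitness = x$best_fitness,
         iterations = length(x$trace), evaluations = x$evaluations)
}

#' Tidy a tuning result
#'
#' @param x A `tune_result` from [tune_svm()].
#' @param ... Unused.
#' @return A tibble with `iteration` and `cv_accuracy` (non-decreasing).
#' @export
tidy.tune_result <- function(x, ...) {
  tibble(iteration = seq_along(x$accuracy_trace),
         cv_accuracy = x$accuracy_trace)
}

#' @rdname tidy.tune_result
#' @export
glance.tune_result <- function(x, ...) {
  tibble(optimizer = x$optimizer, c = x$params$c, g = x$params$g,
         cv_accuracy = 1 - x$result$best_fitness,
         evaluations = x$result$evaluations)
}

#' Tidy a confusion matrix
#'
#' @param x A [confusion()] matrix.
#' @param ... Unused.
#' @return A long tibble with `truth`, `prediction`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  classes <- rownames(x)
  out <- as_tibble(expand.grid(truth = classes, prediction = classes,
                               stringsAsFactors = FALSE))
  out$n <- as.integer(x[cbind(out$truth, out$prediction)])
  out
}

#' Tidy a metrics report
#'
#' @param x A [report()].
#' @param ... Unused.
#' @return A tibble with per-class and macro metrics (one row per metric).
#' @export
tidy.metrics_report <- function(x, ...) {
  classes <- rownames(x$confusion)
  dplyr::bind_rows(
    tibble(class = classes, metric = "recall", value = unname(x$per_class_recall)),
    tibble(class = classes, metric = "precision", value = unname(x$per_class_precision)),
    tibble(class = classes, metric = "f1", value = unname(x$per_class_f1)),
    tibble(class = "macro", metric = c("accuracy", "recall", "precision", "f1",
                                       "kappa_paper", "kappa_cohen"),
           value = c(x$accuracy, x$macro_recall, x$macro_precision,
                     x$macro_f1, x$kappa_paper, x$kappa_cohen))
  )
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_recall = x$macro_recall,
         macro_precision = x$macro_precision, macro_f1 = x$macro_f1,
         kappa_paper = x$kappa_paper, kappa_cohen = x$kappa_cohen)
}

#' Tidy a wavelength-selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with `index` and (when known) `wavelength`.
#' @export
tidy.selection_result <- function(x, ...) {
  out <- tibble(index = x$selected_indices)
  if (!is.null(x$selected_wavelengths)) out$wavelength <- x$selected_wavelengths
  out
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(method = x$method, n_selected = length(x$selected_indices),
         best_cv_error = min(x$diagnostics$cv_error))
}
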