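#' Plot class-mean spectra with dispersion ribbons
#'
#' Mean reflectance per class with a +/- 1 SD ribbon, the standard first look
#' at a labelled spectra set.
#'
#' @param object A spectra set.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_set <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::matches("^R[0-9]"), names_to = "band",
                        values_to = "reflectance") |>
    dplyr::mutate(wavelength = as.numeric(sub("^R", "", .data$band))) |>
    dplyr::group_by(.data$label, .data$wavelength) |>
    dplyr::summarise(mean = mean(.data$reflectance),
                     sd = sd(.data$reflectance), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$mean,
                                     colour = .data$label,
                                     fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                  colour = "class", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot an optimizer convergence trace
#'
#' @param object An `optimizer_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimizer_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = toupper(object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a tile map
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$prediction, .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Compare model metric profiles
#'
#' Bar panel across the five headline axes (accuracy, macro recall, macro
#' precision, macro F1, kappa) for one or more named metric reports — the
#' tabular counterpart of a radar chart.
#'
#' @param reports A named list of [report()] objects.
#' @return A ggplot object.
#' @export
plot_metric_profiles <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports))) names(reports) <- paste0("model", seq_along(reports))
  d <- purrr::imap_dfr(reports, function(r, nm) {
    g <- glance(r)
    tibble(model = nm,
           metric = factor(c("accuracy", "recall", "precision", "F1", "kappa"),
                           levels = c("accuracy", "recall", "precision", "F1",
                                      "kappa")),
           value = c(g$accuracy, g$macro_recall, g$macro_precision,
                     g$macro_f1, g$kappa_paper))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
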