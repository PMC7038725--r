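# ggplot2 views of pipeline outputs.

#' Plot the model-matrix accuracies
#'
#' Bar chart of accuracy per classifier, faceted by model type and
#' modality; CV cells show +/- one fold SD.
#'
#' @param results A `stress_matrix` tibble from [run_model_matrix()].
#' @param eval_method Which evaluation rows to show (default `"cv"` where
#'   available, else all).
#' @return A ggplot object.
#' @export
plot_model_matrix <- function(results, eval_method = NULL) {
  x <- results[!is.na(results$accuracy), , drop = FALSE]
  if (!is.null(eval_method)) x <- x[x$eval_method %in% eval_method, , drop = FALSE]
  ggplot2::ggplot(x, ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                                  fill = .data$modality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$accuracy - .data$fold_sd,
                   ymax = .data$accuracy + .data$fold_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3,
      na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::facet_grid(eval_method ~ model_type) +
    ggplot2::labs(x = NULL, y = "accuracy (%)", fill = "modality") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stress_eval <- function(object, ...) {
  conf <- tidy(object)
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(
      title = sprintf("%s / %s / %s: %.1f%%", object$model_type,
                      object$spec$modality, object$spec$classifier,
                      object$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an EDA decomposition
#'
#' Raw signal with its tonic and phasic components on a shared time axis.
#'
#' @param eda EDA samples (µS).
#' @param decomposition Output of [decompose_eda()] for `eda`.
#' @param fs Sample rate (Hz).
#' @return A ggplot object.
#' @export
plot_eda_decomposition <- function(eda, decomposition, fs = 4) {
  d <- tibble::tibble(
    t = (seq_along(eda) - 1) / fs,
    raw = eda, tonic = decomposition$tonic, phasic = decomposition$phasic
  )
  long <- tidyr::pivot_longer(d, -"t", names_to = "component",
                              values_to = "uS")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$uS,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(mu * S)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
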