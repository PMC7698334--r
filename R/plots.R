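#' Plot spectra
#'
#' Real-channel intensities against chemical shift with the conventional
#' reversed ppm axis, one facet-free overlay colored by class.
#'
#' @param object An `mrs_spectra` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrs_spectra <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$real,
                                       group = .data$sample_id,
                                       colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot class-averaged spectra with the discriminative window highlighted
#'
#' Shows the per-class mean normalized bin intensities and shades the
#' 4.1-3.5 ppm window where the glycine / myo-inositol class differences
#' concentrate.
#'
#' @param averages Output of [average_class_spectra()].
#' @param highlight Two-element ppm window to shade (default `c(3.5, 4.1)`).
#' @return A ggplot object.
#' @export
plot_class_spectra <- function(averages, highlight = c(3.5, 4.1)) {
  long <- tidyr::pivot_longer(averages, c("mean_mut", "mean_wt"),
                              names_to = "class", values_to = "mean")
  long$class <- ifelse(long$class == "mean_mut", "IDHmut", "IDHwt")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ppm_mid, y = .data$mean,
                                     colour = .data$class)) +
    ggplot2::annotate("rect", xmin = min(highlight), xmax = max(highlight),
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "green") +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "mean normalized intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of a nested cross-validation result
#'
#' @param object A `nested_loocv` object.
#' @param ... Unused.
#' @return A ggplot object annotated with the AUC.
#' @export
autoplot.nested_loocv <- function(object, ...) {
  rc <- roc_curve(object, object$positive_class)
  auc <- roc_auc(object, object$positive_class)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC, AUC = %.2f", auc)) +
    ggplot2::theme_minimal()
}

#' Feature selection frequency across outer folds
#'
#' @param object An `mrs_performance` object.
#' @param ... Unused.
#' @return A ggplot object: per-bin selection frequency against chemical
#'   shift, annotated bins labeled by candidate metabolite.
#' @export
autoplot.mrs_performance <- function(object, ...) {
  sel <- object$selection
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$ppm_mid, y = .data$freq)) +
    ggplot2::geom_col(width = min(sel$ppm_upper - sel$ppm_lower)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)",
                  y = "selection frequency (outer folds)") +
    ggplot2::theme_minimal()
}
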