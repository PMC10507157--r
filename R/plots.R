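# ggplot2 autoplot methods for every result type.

#' Plot spectra
#'
#' @param object A `sers_spectra` tibble.
#' @param max_spectra Cap on spectra drawn (default 12).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sers_spectra <- function(object, max_spectra = 12, ...) {
  ids <- head(unique(object$spectrum_id), max_spectra)
  d <- object[object$spectrum_id %in% ids, , drop = FALSE]
  if (!"label" %in% names(d)) d$label <- NA_character_
  ggplot2::ggplot(d, ggplot2::aes(.data$shift, .data$intensity,
                                  group = .data$spectrum_id,
                                  colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)", colour = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_calibration Calibration points and fitted line.
#' @param object A `sers_calibration`.
#' @exportS3Method ggplot2::autoplot
autoplot.sers_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$log10_conc, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(log[10] * "(concentration, v/v)"),
      y = expression(I[1625] / I[1985]),
      title = sprintf("Ratiometric calibration (R² = %.3f)",
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @describeIn confusion_matrix Row-normalized heat map.
#' @param object A `sers_confusion`.
#' @exportS3Method ggplot2::autoplot
autoplot.sers_confusion <- function(object, ...) {
  d <- tidy(object)
  d$true <- factor(d$true, levels = rev(rownames(object$counts)))
  d$predicted <- factor(d$predicted, levels = colnames(object$counts))
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$true,
                                  fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$rate >= 0.01, sprintf("%.2f", .data$rate), "")),
      colour = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  fill = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn evaluate_model One-vs-rest ROC curves.
#' @param object A `sers_eval`.
#' @exportS3Method ggplot2::autoplot
autoplot.sers_eval <- function(object, ...) {
  d <- purrr::imap(object$roc, function(r, cl) {
    tibble::tibble(class = cl, fpr = r$fpr, tpr = r$tpr)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr,
                                  colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("One-vs-rest ROC (macro AUC %.3f)",
                                  object$macro_auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_scores Score plot of the first two components.
#' @param object A `sers_pca`.
#' @exportS3Method ggplot2::autoplot
autoplot.sers_pca <- function(object, ...) {
  evr <- object$explained_variance_ratio
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * evr[2]),
      colour = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn solve_fick_1d Concentration profiles over time.
#' @param object A `concentration_profile`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.concentration_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$time_lab <- sprintf("%g s", d$time)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$concentration,
                                  colour = .data$time_lab)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (m)", y = expression("c (mol/m"^3 * ")"),
                  colour = "time") +
    ggplot2::theme_minimal()
}
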