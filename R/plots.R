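#' Plot class mean spectra with SD ribbons
#'
#' @param x A preprocessed [raman_spectra] tibble with both classes.
#' @param offset Vertical shift applied to the second class to prevent
#'   overlap (default 0).
#' @return A ggplot object.
#' @export
plot_class_profiles <- function(x, offset = 0) {
  prof <- dplyr::bind_rows(
    dplyr::mutate(class_profile(x, "pediatric"), class_label = "pediatric"),
    dplyr::mutate(class_profile(x, "adult"), class_label = "adult",
                  mean = .data$mean + offset)
  )
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$wavenumber, y = .data$mean,
                                     colour = .data$class_label,
                                     fill = .data$class_label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(pediatric = "#2166ac",
                                            adult = "#b2182b"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "Raman shift (1/cm)", y = "Normalized intensity (a.u.)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a subtraction spectrum
#'
#' @param diff Output of [profile_difference()].
#' @param bands Optional band table; assigned bands are marked.
#' @return A ggplot object.
#' @export
plot_profile_difference <- function(diff, bands = NULL) {
  p <- ggplot2::ggplot(diff, ggplot2::aes(x = .data$wavenumber,
                                          y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Raman shift (1/cm)",
                  y = "Mean difference (pediatric - adult)") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_vline(xintercept = bands$position,
                                 colour = "grey80", linewidth = 0.2)
  }
  p
}

#' ROC curve of a classification report
#'
#' @param object A `raman_report` with scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raman_report <- function(object, ...) {
  if (is.null(object$roc)) {
    abort("Report carries no ROC points (no scores were supplied).")
  }
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Negative-second-derivative band attribution plot
#'
#' @param profile A `raman_profile` from [class_profile()].
#' @param window,degree Savitzky-Golay parameters, see
#'   [neg_second_derivative()].
#' @param bands Band table used for labelling assigned peaks.
#' @param tolerance Assignment tolerance in cm^-1.
#' @return A ggplot object.
#' @export
plot_band_attribution <- function(profile, window = 9L, degree = 3L,
                                  bands = band_assignments(),
                                  tolerance = 4) {
  d2 <- neg_second_derivative(profile$mean, profile$wavenumber,
                              window = window, degree = degree)
  pk <- assign_bands(detect_peaks(d2, profile$wavenumber), bands,
                     tolerance = tolerance)
  df <- tibble(wavenumber = profile$wavenumber, d2 = d2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$d2)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Raman shift (1/cm)",
                  y = "-d2 intensity (a.u. per cm^2)") +
    ggplot2::theme_minimal()
  lab <- pk[!is.na(pk$band), ]
  if (nrow(lab)) {
    p <- p + ggplot2::geom_point(data = lab,
                                 ggplot2::aes(x = .data$position,
                                              y = .data$height),
                                 colour = "#b2182b", size = 1) +
      ggplot2::geom_text(data = lab,
                         ggplot2::aes(x = .data$position, y = .data$height,
                                      label = .data$band),
                         angle = 90, hjust = -0.2, size = 2.5,
                         colour = "grey30")
  }
  p
}
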