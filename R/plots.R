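#' Plot a triaxial window and its sum vector
#'
#' Faceted time-series view of the three axes plus the sum-vector
#' magnitude, the usual first look at a candidate fall window.
#'
#' @param accel Data frame with `ax`, `ay`, `az` (one window or a short
#'   stream); a `t` or `time` column is used for the x axis when present.
#' @return A ggplot object.
#' @export
plot_accel_window <- function(accel) {
  accel <- sum_vector(as_accel(accel))
  tcol <- intersect(c("t", "time"), names(accel))
  accel$.t <- if (length(tcol)) accel[[tcol[1]]] else seq_len(nrow(accel))
  long <- tidyr::pivot_longer(
    accel[c(".t", "ax", "ay", "az", "a_sum")],
    cols = c("ax", "ay", "az", "a_sum"),
    names_to = "channel", values_to = "g"
  )
  long$channel <- factor(long$channel, levels = c("ax", "ay", "az", "a_sum"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.t, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = "acceleration (g)") +
    ggplot2::theme_minimal()
}

#' @describeIn multilevel_dwt Coefficient pyramid plot: one facet per level
#'   and coefficient type.
#' @param object A `wavelet_decomposition`.
#' @method autoplot wavelet_decomposition
#' @export
autoplot.wavelet_decomposition <- function(object, ...) {
  long <- tidy(object)
  long$panel <- paste0(long$type, long$level)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free", ncol = 2) +
    ggplot2::labs(x = "coefficient index", y = "value") +
    ggplot2::theme_minimal()
}

#' @describeIn fall_lda Training-score distributions by class with the
#'   decision boundary at zero.
#' @method autoplot fall_lda
#' @export
autoplot.fall_lda <- function(object, ...) {
  if (is.null(object$scores)) {
    abort("model has no stored training scores (restored from JSON?).")
  }
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 50) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "discriminant score (>= 0 classified as fall)",
                  y = "windows", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-class fractal-dimension distributions
#'
#' Boxplots of the four per-level fractal-dimension features split by
#' label, the visual counterpart of the fall-vs-activity irregularity
#' contrast the classifier exploits.
#'
#' @param features Feature tibble from [extract_features()] including a
#'   `label` column.
#' @return A ggplot object.
#' @export
plot_fd_by_class <- function(features) {
  if (!"label" %in% names(features)) {
    abort("`features` must include a `label` column.")
  }
  long <- tidyr::pivot_longer(
    features[c("label", paste0("fd", 1:4))],
    cols = dplyr::starts_with("fd"),
    names_to = "level", values_to = "fd"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$fd,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "fractal dimension", fill = NULL) +
    ggplot2::theme_minimal()
}
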