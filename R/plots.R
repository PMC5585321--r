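# ggplot2 visualisations for the main result types.

#' Biplot of a trait/environment PCA
#'
#' @param object A `trait_pca`.
#' @param axes Which two axes to show.
#' @param colour Optional column of the score table to colour points by
#'   (e.g. `"tropical"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, axes = c(1, 2), colour = NULL, ...) {
  ax <- paste0("PC", axes)
  sc <- object$scores
  ld <- object$loadings
  scale_fac <- 0.8 * min(
    max(abs(sc[[ax[1L]]])) / max(abs(ld[[ax[1L]]])),
    max(abs(sc[[ax[2L]]])) / max(abs(ld[[ax[2L]]]))
  )
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[ax[1L]]], .data[[ax[2L]]]))
  if (!is.null(colour) && colour %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1L]]] * scale_fac,
                   yend = .data[[ax[2L]]] * scale_fac),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data[[ax[1L]]] * scale_fac * 1.08,
                   y = .data[[ax[2L]]] * scale_fac * 1.08,
                   label = .data$variable),
      size = 3, fontface = "bold"
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1L], object$var_frac[axes[1L]]),
      y = sprintf("%s (%.1f%%)", ax[2L], object$var_frac[axes[2L]])
    ) +
    ggplot2::theme_minimal()
}

#' Latitudinal trend plot
#'
#' Observations against absolute latitude with the fitted penalized-spline
#' curve and a pointwise 2-SE band.
#'
#' @param object A `latitude_smooth`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latitude_smooth
#' @export
autoplot.latitude_smooth <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$alat, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_ribbon(
      data = object$curve,
      ggplot2::aes(x = .data$abs_latitude, y = .data$fitted,
                   ymin = .data$fitted - 2 * .data$se,
                   ymax = .data$fitted + 2 * .data$se),
      alpha = 0.2, fill = "steelblue"
    ) +
    ggplot2::geom_line(
      data = object$curve,
      ggplot2::aes(x = .data$abs_latitude, y = .data$fitted),
      colour = "steelblue", linewidth = 1
    ) +
    ggplot2::labs(
      x = "Absolute latitude (degrees)",
      y = if (object$transform == "log") paste0("log ", object$trait)
      else object$trait,
      title = sprintf("%s (edf = %.2f, r2 = %.2f, p = %.3g approx.)",
                      object$trait, object$edf, object$r_squared,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a backward-selected trait model
#'
#' @param object A `trait_model`.
#' @param ... Unused.
#' @return A ggplot of estimates with 95 percent confidence bars.
#' @method autoplot trait_model
#' @export
autoplot.trait_model <- function(object, ...) {
  co <- tidy(object)
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  co$lo <- co$estimate - 1.96 * co$std_error
  co$hi <- co$estimate + 1.96 * co$std_error
  ggplot2::ggplot(co, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Estimate (per SD of predictor)", y = NULL) +
    ggplot2::theme_minimal()
}
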