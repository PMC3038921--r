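#' Plot a reliability sweep
#'
#' Accuracy and coverage as functions of the minimum reliability index.
#'
#' @param object A `nucleo_sweep` from [reliability_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nucleo_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    select(object, "threshold", "coverage", "accuracy"),
    cols = c("coverage", "accuracy"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Minimum reliability index", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class evaluation metrics
#'
#' @param object A `nucleo_eval`.
#' @param ... Unused.
#' @return A ggplot object with sensitivity and PPV per class.
#' @export
autoplot.nucleo_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    select(object$metrics, "class", "sensitivity", "ppv"),
    cols = c("sensitivity", "ppv"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot SILAC ratios with classification rectangles
#'
#' @param silac Tibble with `nuc_cyto_ratio`, `nucpl_cyto_ratio` and
#'   optionally a `silac_group` column (from [classify_silac()]).
#' @param regions A `nucleo_silac_regions`, drawn as rectangles.
#' @return A ggplot object in log2 ratio space.
#' @export
plot_silac_regions <- function(silac, regions) {
  pts <- mutate(silac,
                x = log2(.data$nuc_cyto_ratio),
                y = log2(.data$nucpl_cyto_ratio))
  finite_box <- function(v, lim) ifelse(is.finite(v), v, lim)
  span_x <- range(pts$x); span_y <- range(pts$y)
  rects <- mutate(as_tibble(regions),
                  x_min = finite_box(.data$x_min, span_x[1] - 1),
                  x_max = finite_box(.data$x_max, span_x[2] + 1),
                  y_min = finite_box(.data$y_min, span_y[1] - 1),
                  y_max = finite_box(.data$y_max, span_y[2] + 1))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max,
                   fill = .data$group),
      alpha = 0.15, colour = "grey40"
    )
  if ("silac_group" %in% names(pts)) {
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = .data$y,
                                              colour = .data$silac_group),
                                 size = 1)
  } else {
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = .data$y), size = 1)
  }
  p +
    ggplot2::labs(x = "log2 nucleolar / cytoplasmic ratio",
                  y = "log2 nucleoplasmic / cytoplasmic ratio",
                  fill = "region", colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot conservation fractions with bootstrap error bars
#'
#' @param fractions Tibble from [conservation_fractions()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(fractions) {
  fractions <- mutate(fractions,
                      organism = factor(.data$organism, levels = unique(.data$organism)))
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$organism, y = .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fraction - .data$sd,
                   ymax = .data$fraction + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "Fraction with orthologue", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
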