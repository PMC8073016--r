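#' Heatmap of a chromatin activity landscape
#'
#' Cells (lineal order) by integration positions (genome order), coloured
#' by consensus activity; replicate-variable entries are overlaid with
#' points.
#'
#' @param object An `activity_landscape`.
#' @param show_variable Overlay replicate-variable calls?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_landscape <- function(object, show_variable = TRUE, ...) {
  df <- tidy(object) %>%
    mutate(cell = factor(.data$cell, levels = rev(object$cells)),
           site_id = factor(.data$site_id,
                            levels = colnames(object$activity)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$cell)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$activity)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "activity\n(log2)") +
    ggplot2::labs(x = "integration site", y = "cell") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
  if (show_variable && any(df$variable %in% TRUE)) {
    p <- p + ggplot2::geom_point(data = filter(df, .data$variable %in% TRUE),
                                 size = 0.3, colour = "white")
  }
  p
}

#' Divergence as a function of lineage distance
#'
#' @param dm A `divergence_matrix`.
#' @param even_only Restrict to even lineage distances.
#' @return A ggplot object (mean +/- SD per distance).
#' @export
plot_divergence_by_distance <- function(dm, even_only = TRUE) {
  df <- divergence_by_lineage_distance(dm, even_only = even_only)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lineage_distance,
                                   y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lineage distance (cell divisions)",
                  y = "chromatin activity divergence") +
    ggplot2::theme_classic()
}

#' Volcano-style view of transition calls
#'
#' Transition score against the worse of the two adjusted p-values.
#'
#' @param object A `transition_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_calls <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(q = pmax(.data$q1, .data$q2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transition_score,
                                   y = -log10(.data$q),
                                   colour = .data$is_transition)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = "transition") +
    ggplot2::labs(x = "transition score (mean inter / intra)",
                  y = "-log10 adjusted p (max of daughters)") +
    ggplot2::theme_classic()
}

#' Objective curve of an attenuation fit
#'
#' @param object An `attenuation_fit`.
#' @param ... Unused.
#' @return A ggplot object of mean matched-cell correlation versus alpha.
#' @export
autoplot.attenuation_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$alpha,
                                            y = .data$mean_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = expression(alpha~"(per-plane attenuation)"),
                  y = "mean VNO/DNO matched-cell correlation") +
    ggplot2::theme_classic()
}
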