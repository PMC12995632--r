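# ggplot2 views of the pipeline's tabular results.

#' Plot a section with optional detection overlay
#'
#' @param stack A `section_stack`.
#' @param index Section index.
#' @param channel Channel name (default first channel).
#' @param detections Optional `soma_detections` for this section.
#' @return A ggplot object.
#' @export
plot_section <- function(stack, index = 1, channel = NULL, detections = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  chs <- names(stack$sections[[index]]$channels)
  if (is.null(channel)) channel <- chs[1]
  img <- stack$sections[[index]]$channels[[channel]]
  df <- tibble::tibble(
    y = as.vector(row(img)) - 1,
    x = as.vector(col(img)) - 1,
    intensity = as.vector(img)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black",
                                 high = if (channel == "blue") "steelblue1" else "green3") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = stack$metadata$section_id[index],
                  x = "x (px)", y = "y (px)", fill = channel) +
    ggplot2::theme_minimal()
  if (!is.null(detections) && nrow(detections)) {
    p <- p + ggplot2::geom_point(
      data = detections, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 1, colour = "red", size = 2
    )
  }
  p
}

#' Per-section count dot plot by region and genotype
#'
#' Mirrors the usual presentation of per-section cell counts: one dot per
#' section, grouped by region, coloured by genotype, with group means.
#'
#' @param object A `section_counts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.section_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region_name, y = .data$count,
                                       colour = .data$genotype)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.15, dodge.width = 0.6), alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          position = ggplot2::position_dodge(width = 0.6),
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "somata per section", colour = "genotype") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Effect-size plot of a region comparison table
#'
#' Percent change per region with BH significance stars.
#'
#' @param object A `region_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_comparison <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$percent_change))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_name,
                                   y = .data$percent_change,
                                   fill = .data$significant_bh)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       vjust = ifelse(df$percent_change < 0, 1.4, -0.4)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = "BH significant") +
    ggplot2::labs(x = NULL, y = "genotype effect (% of reference mean)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
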