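#' Plot a variation graph as a diamond diagram
#'
#' Lays nodes out left to right in ID order (the reference backbone at y = 0,
#' alternative-allele nodes raised above it) with edges drawn as segments.
#' Intended for small graphs; label drawing is disabled above `max_labels`
#' nodes.
#'
#' @param object A `vg_graph`.
#' @param max_labels Maximum number of nodes to label with their sequence.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot vg_graph
autoplot.vg_graph <- function(object, max_labels = 50, ...) {
  nodes <- tidy(object)
  nodes$x <- cumsum(dplyr::lag(nodes$length, default = 0) + 2) -
    ifelse(nodes$allele == "alt", nodes$length + 2, 0)
  nodes$y <- ifelse(nodes$allele == "alt", 1, 0)
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     dplyr::select(nodes, from = "id", x0 = "x", y0 = "y",
                                   l0 = "length"),
                     by = "from"),
    dplyr::select(nodes, to = "id", x1 = "x", y1 = "y"), by = "to")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0 + .data$l0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      colour = "grey50") +
    ggplot2::geom_segment(
      data = nodes,
      ggplot2::aes(x = .data$x, xend = .data$x + .data$length, y = .data$y,
                   yend = .data$y, colour = .data$allele),
      linewidth = 4, lineend = "round") +
    ggplot2::scale_colour_manual(
      values = c(none = "grey30", ref = "#1b9e77", alt = "#d95f02")) +
    ggplot2::labs(x = "offset (bp, schematic)", y = NULL, colour = "node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(nodes) <= max_labels) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x + .data$length / 2, y = .data$y + 0.15,
                   label = paste0(.data$id, ":", .data$seq)),
      size = 3)
  }
  p
}

#' Plot evaluation metrics
#'
#' @param object A `vg_eval`.
#' @param ... Unused.
#' @return A ggplot bar chart of precision, sensitivity and F-measure.
#' @export
#' @method autoplot vg_eval
autoplot.vg_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(glance(object),
                           c("precision", "sensitivity", "f_measure"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "value",
                  subtitle = sprintf("TP %d, FP %d, FN %d", object$tp,
                                     object$fp, object$fn)) +
    ggplot2::theme_minimal()
}

#' Plot per-site allele support
#'
#' Reference versus alternative allele depth per SNP site, optionally
#' coloured by called genotype when the input carries a `genotype` column.
#'
#' @param support Tibble from [snp_support()] or [call_genotypes()].
#' @return A ggplot object.
#' @export
plot_allele_support <- function(support) {
  support <- as_tibble(support)
  if (!"ref_count" %in% names(support) && "ref_depth" %in% names(support)) {
    support <- dplyr::rename(support, ref_count = "ref_depth",
                             alt_count = "alt_depth")
  }
  aes <- if ("genotype" %in% names(support)) {
    ggplot2::aes(x = .data$ref_count, y = .data$alt_count,
                 colour = .data$genotype)
  } else {
    ggplot2::aes(x = .data$ref_count, y = .data$alt_count)
  }
  ggplot2::ggplot(support, aes) +
    ggplot2::geom_jitter(width = 0.2, height = 0.2, alpha = 0.6) +
    ggplot2::labs(x = "reference allele depth", y = "alternative allele depth") +
    ggplot2::theme_minimal()
}
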