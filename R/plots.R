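# ggplot2 visualisations -----------------------------------------------------

#' @export
autoplot.diversity_profile <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(alpha_label = factor(
      ifelse(is.infinite(.data$alpha), "Inf", format(.data$alpha)),
      levels = ifelse(is.infinite(object$alpha), "Inf",
                      format(object$alpha))
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha_label, .data$entropy,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(alpha),
      y = sprintf("Renyi entropy (log base %s)", attr(object, "base")),
      title = sprintf("Diversity profile: %s", attr(object, "sample_id"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcr_pwm <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$position, .data$prob,
                               fill = .data$aa, label = .data$aa)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.5) +
    ggplot2::scale_x_continuous(breaks = seq_len(attr(object, "seq_length"))) +
    ggplot2::labs(x = "CDR3 position", y = "probability",
                  title = sprintf("Sequence logo (n = %d)",
                                  attr(object, "support"))) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcr_network <- function(object, seed = 1, ...) {
  g <- object$graph
  layout <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tidy(object, "nodes") |>
    dplyr::mutate(x = layout[, 1], y = layout[, 2])
  edges <- tidy(object, "edges")
  edge_df <- dplyr::left_join(
    edges, dplyr::select(nodes, "cdr3_aa", x0 = "x", y0 = "y"),
    by = c(from = "cdr3_aa")
  ) |>
    dplyr::left_join(dplyr::select(nodes, "cdr3_aa", x1 = "x", y1 = "y"),
                     by = c(to = "cdr3_aa"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y))
  if (nrow(edge_df)) {
    p <- p + ggplot2::geom_segment(
      data = edge_df,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(
      size = .data$frequency,
      colour = factor(.data$community)
    )) +
    ggplot2::labs(colour = "community", size = "frequency") +
    ggplot2::theme_void()
}

#' @export
autoplot.tcr_embedding <- function(object, new_points = NULL, ...) {
  p <- ggplot2::ggplot(object$coordinates,
                       ggplot2::aes(.data$dim1, .data$dim2,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "group") +
    ggplot2::theme_minimal()
  if (!is.null(new_points)) {
    p <- p + ggplot2::geom_point(
      data = new_points,
      ggplot2::aes(.data$dim1, .data$dim2),
      inherit.aes = FALSE, shape = 17, size = 3, colour = "black"
    )
  }
  p
}

#' Quick feature plots
#'
#' Convenience wrappers around the tabular feature outputs.
#'
#' @param rep A `tcr_repertoire`.
#' @param weighted Passed through to the underlying statistic.
#' @param top_n Number of clones shown individually.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(rep, weighted = FALSE) {
  ggplot2::ggplot(length_distribution(rep, weighted = weighted),
                  ggplot2::aes(.data$length, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "CDR3 length (aa)",
                  y = if (weighted) "clone frequency" else "unique sequences") +
    ggplot2::theme_minimal()
}

#' @rdname plot_length_distribution
#' @param segment `"V"` or `"J"`.
#' @export
plot_gene_usage <- function(rep, segment = "V", weighted = FALSE) {
  usage <- gene_usage(rep, segment = segment, weighted = weighted)
  ggplot2::ggplot(usage, ggplot2::aes(
    stats::reorder(.data$gene, -.data$frequency), .data$frequency
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("%s gene", segment), y = "usage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_length_distribution
#' @export
plot_vj_pairing <- function(rep, weighted = FALSE) {
  ggplot2::ggplot(vj_pairing(rep, weighted = weighted),
                  ggplot2::aes(.data$j_gene, .data$v_gene,
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "J gene", y = "V gene", fill = "pair frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_length_distribution
#' @export
plot_clonal_composition <- function(rep, top_n = 10) {
  comp <- clonal_composition(rep, top_n = top_n)
  df <- tibble::as_tibble(comp) |>
    dplyr::bind_rows(tibble::tibble(
      cdr3_aa = "other", frequency = attr(comp, "other_frequency")
    )) |>
    dplyr::mutate(cdr3_aa = factor(.data$cdr3_aa, levels = rev(.data$cdr3_aa)))
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$frequency,
                                   fill = .data$cdr3_aa)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(fill = "clone") +
    ggplot2::theme_void()
}
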