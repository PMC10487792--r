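#' Kaplan-Meier curves for a survival comparison
#'
#' Step curves per subtype over the comparison horizon.
#'
#' @param x A `surv_comparison` from [survival_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_km <- function(x, ...) {
  stopifnot(inherits(x, "surv_comparison"))
  curves <- x$curves |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x[c("time", "surv")])) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster = factor(.data$cluster))
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$surv,
                                       colour = .data$cluster)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival", colour = "Subtype") +
    ggplot2::theme_minimal()
}

#' @rdname plot_km
#' @param object A `surv_comparison`.
#' @export
autoplot.surv_comparison <- function(object, ...) plot_km(object, ...)

#' Heatmap of a cluster-score matrix
#'
#' Genes are ordered by group (if a grouping is supplied) or by the
#' average-linkage dendrogram of the score profiles.
#'
#' @param cs A [cs_matrix()].
#' @param grouping Optional `cluster_grouping` used to order genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cs_heatmap <- function(cs, grouping = NULL, ...) {
  stopifnot(inherits(cs, "cs_matrix"))
  ord <- if (!is.null(grouping)) {
    grouping$gene[order(grouping$group)]
  } else {
    rownames(cs)[hclust(as.dist(2 - unclass(cs)), method = "average")$order]
  }
  m <- unclass(cs)[ord, ord]
  df <- tibble::as_tibble(m, rownames = "gene_i") |>
    tidyr::pivot_longer(-"gene_i", names_to = "gene_j", values_to = "cs") |>
    dplyr::mutate(gene_i = factor(.data$gene_i, levels = ord),
                  gene_j = factor(.data$gene_j, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_i, .data$gene_j,
                                   fill = .data$cs)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0.5, limits = c(-1, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Representative versus perturbation score per candidate gene
#'
#' One panel per group; selected genes highlighted.
#'
#' @param signature A `signature_set` from [select_signature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(signature, ...) {
  stopifnot(inherits(signature, "signature_set"))
  ggplot2::ggplot(signature,
                  ggplot2::aes(.data$rs01, .data$ps, colour = .data$selected)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~ group, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = "Representative score (rescaled)",
                  y = "Perturbation score", colour = "Selected") +
    ggplot2::theme_minimal()
}

#' @rdname plot_signature_scores
#' @param object A `signature_set`.
#' @export
autoplot.signature_set <- function(object, ...) plot_signature_scores(object, ...)
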