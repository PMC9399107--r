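#' Heatmap of an Ro/e table
#'
#' Tiles colored by Ro/e with the convention that values above 1 indicate
#' tissue enrichment; undefined entries are blank.
#'
#' @param object A `roe_table` from [roe()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roe_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$col_key]],
                                   y = .data[[object$row_key]],
                                   fill = .data$roe)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$roe)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "grey90") +
    ggplot2::labs(fill = "Ro/e") +
    ggplot2::theme_minimal()
}

#' Heatmap of a clonotype-sharing matrix
#'
#' @param object A `sharing_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sharing_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$secondary, y = .data$primary,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "secondary cluster", y = "primary cluster",
                  fill = "shared\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean CNV profile along the genome per cell group
#'
#' Averages the profile within groups of cells (e.g. cluster labels) and
#' draws it against genomic gene order, faceted by chromosome.
#'
#' @param object A `cnv_profile` from [infer_cnv()].
#' @param groups Named character vector mapping cell ids to group labels;
#'   defaults to a single "all cells" group.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_profile <- function(object, groups = NULL, ...) {
  cells <- rownames(object$values)
  groups <- groups %||% setNames(rep("all cells", length(cells)), cells)
  df <- tibble(cell_id = cells, group = unname(groups[cells])) |>
    filter(!is.na(.data$group))
  prof <- do.call(rbind, lapply(split(df$cell_id, df$group), function(ids) {
    colMeans(object$values[ids, , drop = FALSE])
  }))
  long <- as_tibble(as.data.frame.table(prof, responseName = "value",
                                        stringsAsFactors = FALSE))
  names(long)[1:2] <- c("group", "gene_id")
  long$order <- match(long$gene_id, object$genes$gene_id)
  long$chromosome <- object$genes$chromosome[long$order]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order, y = .data$value,
                                     color = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "genes in genomic order", y = "CNV deviation") +
    ggplot2::theme_minimal()
}

#' Real versus permuted clonal-aggregation statistics
#'
#' @param object An `aggregation_test`.
#' @param ... Unused.
#' @return A ggplot object (violin + box of the two statistic vectors).
#' @export
autoplot.aggregation_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$statistic)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "max within-cluster proportion",
                  subtitle = sprintf("%s: p = %.3g", object$compartment,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' VDJ-usage embedding scatter
#'
#' @param object A `vdj_embedding`.
#' @param components Two components to draw (default PC1/PC2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdj_embedding <- function(object, components = c("PC1", "PC2"), ...) {
  df <- object$coordinates
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[components[1]]],
                                   y = .data[[components[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1],
                  100 * object$explained_variance[1]),
      y = sprintf("%s (%.1f%%)", components[2],
                  100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Ligand-receptor network edge heatmap
#'
#' Sections on both axes, tiles sized by the number of significant
#' interactions and colored by the proportion of eligible patients with a
#' significant interaction.
#'
#' @param object An `lr_network` from [aggregate_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lr_network <- function(object, ...) {
  ggplot2::ggplot(object$edges,
                  ggplot2::aes(x = .data$section_a, y = .data$section_b)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_interactions,
                                     color = .data$prop_patients)) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(size = "significant\ninteractions",
                  color = "patient\nproportion", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
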