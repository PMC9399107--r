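#' Tidy an Ro/e table into a long tibble
#'
#' @param x A `roe_table` from [roe()].
#' @param ... Unused.
#' @return A tibble with the row key, column key, `observed`, `expected`,
#'   `roe`.
#' @export
tidy.roe_table <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$roe, responseName = "roe",
                                        stringsAsFactors = FALSE))
  names(long)[1:2] <- c(x$row_key, x$col_key)
  long$observed <- as.vector(x$observed)
  long$expected <- as.vector(x$expected)
  long[, c(x$row_key, x$col_key, "observed", "expected", "roe")]
}

#' Tidy a clonotype-sharing matrix into a long tibble
#'
#' @param x A `sharing_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `primary`, `secondary`, `fraction`.
#' @export
tidy.sharing_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "fraction",
                                stringsAsFactors = FALSE))
}

#' Tidy a clonal-aggregation test: per-clonotype statistics
#'
#' @param x An `aggregation_test`.
#' @param ... Unused.
#' @return A tibble with columns `type` ("real"/"permuted") and `statistic`.
#' @export
tidy.aggregation_test <- function(x, ...) {
  bind_rows(tibble(type = "real", statistic = x$real_stats),
            tibble(type = "permuted", statistic = x$perm_stats))
}

#' One-row summary of a clonal-aggregation test
#'
#' @param x An `aggregation_test`.
#' @param ... Unused.
#' @return A tibble with `compartment`, `n_clonotypes`, `n_perm`,
#'   `median_real`, `median_permuted`, `p_value`.
#' @export
glance.aggregation_test <- function(x, ...) {
  tibble(compartment = x$compartment, n_clonotypes = x$n_clonotypes,
         n_perm = x$n_perm, median_real = median(x$real_stats),
         median_permuted = median(x$perm_stats), p_value = x$p_value)
}

#' Tidy a CNV profile into a long tibble
#'
#' @param x A `cnv_profile`.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `gene_id`, `chromosome`, `value`.
#' @export
tidy.cnv_profile <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$values, responseName = "value",
                                        stringsAsFactors = FALSE))
  names(long)[1:2] <- c("cell_id", "gene_id")
  long$chromosome <- x$genes$chromosome[match(long$gene_id, x$genes$gene_id)]
  long[, c("cell_id", "gene_id", "chromosome", "value")]
}

#' Tidy a VDJ-usage embedding: per-cluster coordinates
#'
#' @param x A `vdj_embedding`.
#' @param ... Unused.
#' @return The coordinates tibble (cluster plus PC columns).
#' @export
tidy.vdj_embedding <- function(x, ...) x$coordinates

#' One-row-per-component summary of a VDJ-usage embedding
#'
#' @param x A `vdj_embedding`.
#' @param ... Unused.
#' @return A tibble with `component` and `explained_variance`.
#' @export
glance.vdj_embedding <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained_variance)),
         explained_variance = x$explained_variance)
}

#' Tidy a ligand-receptor network: its edge list
#'
#' @param x An `lr_network` from [aggregate_network()].
#' @param ... Unused.
#' @return The edges tibble (Cytoscape-style source/target columns first).
#' @export
tidy.lr_network <- function(x, ...) {
  rename(x$edges, source = "section_a", target = "section_b")
}

#' One-row summary of a ligand-receptor network
#'
#' @param x An `lr_network`.
#' @param ... Unused.
#' @return A tibble with `n_sections`, `n_edges`, `n_interactions`, `alpha`.
#' @export
glance.lr_network <- function(x, ...) {
  tibble(n_sections = nrow(x$nodes), n_edges = nrow(x$edges),
         n_interactions = sum(x$edges$n_interactions), alpha = x$alpha)
}
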