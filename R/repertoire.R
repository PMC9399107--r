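#' Flag TCR doublets
#'
#' A cell is flagged when it carries more than 2 productive TRA or more than
#' 2 productive TRB chains. Cells with exactly two chains of either type are
#' kept (dual-TRA and dual-TRB T cells are a known, quantified population).
#'
#' @param contigs Contig tibble from [read_contigs()].
#' @return A tibble with columns `cell_id` and `tcr_doublet` covering every
#'   cell present in `contigs`.
#' @export
flag_tcr_doublets <- function(contigs) {
  .require_cols(contigs, c("cell_id", "chain", "productive"), "contig table")
  contigs |>
    filter(.data$productive) |>
    count(.data$cell_id, .data$chain) |>
    group_by(.data$cell_id) |>
    summarise(tcr_doublet = any(.data$n > 2), .groups = "drop") |>
    dplyr::right_join(distinct(contigs, .data$cell_id), by = "cell_id") |>
    mutate(tcr_doublet = !is.na(.data$tcr_doublet) & .data$tcr_doublet)
}

#' Assemble clonotypes from TCR contigs
#'
#' Cells of one patient sharing an identical multiset of productive
#' (chain, CDR3) sequences belong to one clonotype; identical sequences in
#' different patients form distinct clonotypes (clonotypes are merged across
#' samples *within* a patient only). Cells without a productive TRB chain
#' are excluded from the T-cell analysis set, as are TCR doublets.
#'
#' @param contigs Contig tibble from [read_contigs()].
#' @param cells Cell metadata tibble with `cell_id`, `patient` and, when
#'   available, `tissue`, `cluster`, `compartment` (carried through).
#' @param key Sequence level defining identity: `"cdr3_nt"` (default,
#'   strictest) or `"cdr3_aa"`.
#' @param drop_doublets Remove cells flagged by [flag_tcr_doublets()]
#'   (default TRUE).
#' @return A tibble of class `clonotype_table` with one row per T cell:
#'   `cell_id`, `patient`, `clonotype_id`, `clone_size` plus any carried
#'   metadata columns. `clone_size` is the number of member cells of the
#'   cell's clonotype.
#' @export
assign_clonotypes <- function(contigs, cells, key = c("cdr3_nt", "cdr3_aa"),
                              drop_doublets = TRUE) {
  key <- match.arg(key)
  .require_cols(contigs, c("cell_id", "chain", "productive", key), "contig table")
  .require_cols(cells, c("cell_id", "patient"), "cell table")
  orphans <- setdiff(unique(contigs$cell_id), cells$cell_id)
  if (length(orphans)) {
    warn(sprintf("dropping %d contig cell id(s) absent from the cell table",
                 length(orphans)))
  }
  prod <- filter(contigs, .data$productive, .data$cell_id %in% cells$cell_id)
  if (drop_doublets) {
    doublets <- filter(flag_tcr_doublets(contigs), .data$tcr_doublet)$cell_id
    prod <- filter(prod, !.data$cell_id %in% doublets)
  }
  # canonical identity key: sorted multiset of (chain, sequence)
  keys <- prod |>
    mutate(chain_seq = paste(.data$chain, .data[[key]], sep = ":")) |>
    group_by(.data$cell_id) |>
    summarise(tcr_key = paste(sort(.data$chain_seq), collapse = "|"),
              has_trb = any(.data$chain == "TRB"), .groups = "drop") |>
    filter(.data$has_trb)
  meta_cols <- intersect(c("patient", "tissue", "cluster", "compartment"),
                         names(cells))
  out <- keys |>
    inner_join(cells[, c("cell_id", meta_cols)], by = "cell_id") |>
    group_by(.data$patient) |>
    mutate(clonotype_id = paste0(.data$patient, "_ct",
                                 formatC(dplyr::dense_rank(.data$tcr_key),
                                         width = 4, flag = "0"))) |>
    ungroup() |>
    group_by(.data$clonotype_id) |>
    mutate(clone_size = n()) |>
    ungroup() |>
    select("cell_id", dplyr::all_of(meta_cols), "clonotype_id", "clone_size",
           "tcr_key") |>
    arrange(.data$patient, .data$clonotype_id, .data$cell_id)
  class(out) <- c("clonotype_table", class(out))
  out
}

#' Clonal expansion score per cluster
#'
#' The expansion score of a cluster is the fraction of its TCR-bearing cells
#' that belong to clonal clonotypes (clone size >= `min_size`, default 2).
#'
#' @param clonotypes A `clonotype_table` from [assign_clonotypes()] carrying
#'   a `cluster` column.
#' @param min_size Minimum clone size counted as clonal (default 2).
#' @return A tibble with columns `cluster`, `n_cells`, `expansion_score`.
#' @export
expansion_score <- function(clonotypes, min_size = 2) {
  .require_cols(clonotypes, c("cluster", "clone_size"), "clonotype table")
  if (!nrow(clonotypes)) {
    abort("no TCR-bearing cells", class = "clonotrace_validation_error")
  }
  clonotypes |>
    group_by(.data$cluster) |>
    summarise(n_cells = n(),
              expansion_score = mean(.data$clone_size >= min_size),
              .groups = "drop")
}

#' Morisita-Horn index between two clone-size vectors
#'
#' `2 * sum(T_i * B_i) / sum(T_i^2 + B_i^2)` with `T_i = t_i / sum(t)` and
#' `B_i = b_i / sum(b)`, over the union of clonotypes observed in either
#' compartment. 1 for identical relative compositions, 0 for disjoint
#' repertoires; symmetric and invariant to scaling either vector.
#'
#' @param t_sizes,b_sizes Named non-negative numeric vectors of clone sizes
#'   (names are clonotype ids); at least one positive entry each.
#' @return The index, a number in \[0, 1\].
#' @export
morisita_horn_index <- function(t_sizes, b_sizes) {
  if (!sum(t_sizes) || !sum(b_sizes)) {
    abort("both compartments need at least one clone",
          class = "clonotrace_validation_error")
  }
  ids <- union(names(t_sizes), names(b_sizes))
  t <- setNames(numeric(length(ids)), ids)
  b <- t
  t[names(t_sizes)] <- t_sizes
  b[names(b_sizes)] <- b_sizes
  T_i <- t / sum(t)
  B_i <- b / sum(b)
  2 * sum(T_i * B_i) / sum(T_i^2 + B_i^2)
}

#' Morisita-Horn blood-tissue repertoire overlap per cluster
#'
#' For each cluster, cells are split into blood versus solid tissue (tumor
#' plus paratumor pooled by default) and the Morisita-Horn index is computed
#' over the clone-size distributions of the two compartments. Clusters with
#' an empty compartment get `NA` (undefined, not zero).
#'
#' @param clonotypes A `clonotype_table` carrying `cluster` and `tissue`.
#' @param solid Which tissues count as the solid compartment: `"pooled"`
#'   (tumor + paratumor, default) or `"tumor"`.
#' @return A tibble with columns `cluster`, `index`, `n_shared_clonotypes`,
#'   `blood_total`, `tissue_total`.
#' @export
morisita_horn <- function(clonotypes, solid = c("pooled", "tumor")) {
  solid <- match.arg(solid)
  .require_cols(clonotypes, c("cluster", "tissue", "clonotype_id"), "clonotype table")
  solid_tissues <- if (solid == "pooled") c("tumor", "paratumor") else "tumor"
  clonotypes |>
    group_by(.data$cluster) |>
    dplyr::group_modify(function(df, key) {
      bl <- df$clonotype_id[df$tissue == "blood"]
      ti <- df$clonotype_id[df$tissue %in% solid_tissues]
      if (!length(bl) || !length(ti)) {
        return(tibble(index = NA_real_,
                      n_shared_clonotypes = NA_integer_,
                      blood_total = length(bl), tissue_total = length(ti)))
      }
      b <- table(bl); t <- table(ti)
      tibble(index = morisita_horn_index(c(t), c(b)),
             n_shared_clonotypes = length(intersect(names(b), names(t))),
             blood_total = length(bl), tissue_total = length(ti))
    }) |>
    ungroup()
}

#' Clonotype-sharing matrix between clusters
#'
#' Entry (r, c) is the fraction of clonotypes with at least one cell in the
#' primary cluster r that also have at least one cell in the secondary
#' cluster c; the diagonal is 1 by construction and rows are independent.
#' By default only clonal clonotypes (clone size >= 2) qualify; a row whose
#' primary cluster has no qualifying clonotype is `NA`.
#'
#' @param clonotypes A `clonotype_table` carrying `cluster`.
#' @param clonal_only Restrict to clonal clonotypes (default TRUE).
#' @return An object of class `sharing_matrix`: the fraction matrix with a
#'   `n_clonotypes` attribute (qualifying clonotypes per primary cluster).
#' @export
sharing_matrix <- function(clonotypes, clonal_only = TRUE) {
  .require_cols(clonotypes, c("cluster", "clonotype_id", "clone_size"),
                "clonotype table")
  df <- if (clonal_only) filter(clonotypes, .data$clone_size >= 2) else clonotypes
  clusters <- sort(unique(clonotypes$cluster))
  inc <- table(df$clonotype_id, factor(df$cluster, levels = clusters)) > 0
  m <- matrix(NA_real_, length(clusters), length(clusters),
              dimnames = list(primary = clusters, secondary = clusters))
  n_primary <- colSums(inc)
  for (r in seq_along(clusters)) {
    in_r <- inc[, r]
    if (!sum(in_r)) next
    m[r, ] <- colSums(inc[in_r, , drop = FALSE]) / sum(in_r)
  }
  structure(m, n_clonotypes = n_primary, class = c("sharing_matrix", "matrix"))
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat(sprintf("<sharing_matrix> %d clusters (n clonotypes per primary: %s)\n",
              nrow(x), paste(attr(x, "n_clonotypes"), collapse = ", ")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Clonal-aggregation permutation test
#'
#' Tests whether clonotypes concentrate in single phenotype clusters more
#' than expected under label exchangeability. The per-clonotype statistic is
#' the maximum, over clusters, of the proportion of that clonotype's cells
#' falling in the cluster. The null vector is obtained by shuffling cluster
#' labels across all compartment cells (cluster sizes preserved) and
#' recomputing; `n_perm` replicates are pooled. The reported p-value is a
#' two-sided Wilcoxon rank-sum test between the real and permuted vectors.
#'
#' @param clonotypes A `clonotype_table` carrying `cluster` and
#'   `compartment`.
#' @param compartment Compartment to test (e.g. `"CD8"`); `NULL` uses all
#'   cells.
#' @param n_perm Number of label-shuffle replicates (default 1).
#' @param seed Integer seed.
#' @param min_size Minimum clonotype size (within the compartment) to enter
#'   the test (default 2).
#' @return An object of class `aggregation_test`: list with `compartment`,
#'   `real_stats`, `perm_stats`, `p_value`, `n_clonotypes`.
#' @export
clonal_aggregation_test <- function(clonotypes, compartment = NULL,
                                    n_perm = 1, seed = 1L, min_size = 2) {
  .require_cols(clonotypes, c("cluster", "clonotype_id"), "clonotype table")
  df <- clonotypes
  if (!is.null(compartment)) {
    .require_cols(df, "compartment", "clonotype table")
    df <- filter(df, .data$compartment == !!compartment)
  }
  if (length(unique(df$cluster)) < 2) {
    abort("need at least 2 clusters in the compartment",
          class = "clonotrace_validation_error")
  }
  keep <- df |>
    count(.data$clonotype_id) |>
    filter(.data$n >= min_size)
  if (nrow(keep) < 10) {
    abort("need at least 10 clonotypes at or above min_size",
          class = "clonotrace_validation_error")
  }
  ct <- factor(df$clonotype_id)
  cl <- factor(df$cluster)
  sel <- levels(ct) %in% keep$clonotype_id
  max_prop <- function(cluster_labels) {
    tab <- table(ct, cluster_labels)
    (apply(tab, 1, max) / rowSums(tab))[sel]
  }
  real_stats <- max_prop(cl)
  perm_stats <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(i) max_prop(sample(cl))))
  })
  p <- suppressWarnings(
    wilcox.test(real_stats, perm_stats, alternative = "two.sided")$p.value)
  structure(list(compartment = compartment %||% "all",
                 real_stats = unname(real_stats),
                 perm_stats = unname(perm_stats),
                 p_value = p, n_clonotypes = sum(sel), n_perm = n_perm),
            class = "aggregation_test")
}

#' @export
print.aggregation_test <- function(x, ...) {
  cat(sprintf(
    "<aggregation_test> %s: %d clonotypes, median real %.3f vs permuted %.3f, p = %.3g\n",
    x$compartment, x$n_clonotypes, median(x$real_stats),
    median(x$perm_stats), x$p_value))
  invisible(x)
}

#' PCA embedding of clusters by VDJ-gene usage
#'
#' Builds a clusters x VDJ-genes usage matrix (TRA and TRB pooled): each
#' entry is the fraction of the cluster's productive chains carrying that
#' V, D or J gene. Columns are z-scored across clusters (zero-variance
#' columns dropped) and the top principal components are returned.
#'
#' @param contigs Contig tibble from [read_contigs()].
#' @param cells Cell metadata with `cell_id` and `cluster`; cells without a
#'   cluster are ignored.
#' @param n_components Number of components (default 3); needs at least
#'   `n_components + 1` clusters.
#' @return An object of class `vdj_embedding`: list with `coordinates`
#'   (tibble: cluster + PC columns), `explained_variance` (fractions),
#'   `usage` (the raw usage matrix), `loadings`.
#' @export
vdj_usage_embedding <- function(contigs, cells, n_components = 3) {
  .require_cols(contigs, c("cell_id", "chain", "productive"), "contig table")
  .require_cols(cells, c("cell_id", "cluster"), "cell table")
  chains <- contigs |>
    filter(.data$productive) |>
    inner_join(cells[, c("cell_id", "cluster")], by = "cell_id")
  long <- chains |>
    mutate(.chain_id = row_number()) |>
    tidyr::pivot_longer(cols = c("v_gene", "d_gene", "j_gene"),
                        names_to = "segment", values_to = "gene") |>
    filter(!is.na(.data$gene), .data$gene != "", .data$gene != "None")
  if (!nrow(long)) {
    abort("no VDJ gene observed", class = "clonotrace_validation_error")
  }
  n_chains <- chains |> count(.data$cluster, name = "n_chains")
  usage <- long |>
    count(.data$cluster, .data$gene) |>
    left_join(n_chains, by = "cluster") |>
    mutate(freq = .data$n / .data$n_chains) |>
    select("cluster", "gene", "freq") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "freq",
                       values_fill = 0)
  mat <- as.matrix(usage[, -1, drop = FALSE])
  rownames(mat) <- usage$cluster
  if (nrow(mat) < n_components + 1) {
    abort("need more clusters than components", class = "clonotrace_validation_error")
  }
  sds <- apply(mat, 2, sd)
  z <- scale(mat[, sds > 0, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- as_tibble(pc$x[, seq_len(k), drop = FALSE], rownames = "cluster")
  structure(list(coordinates = coords,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 usage = mat,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE]),
            class = "vdj_embedding")
}

#' @export
print.vdj_embedding <- function(x, ...) {
  cat(sprintf("<vdj_embedding> %d clusters x %d genes; variance explained: %s\n",
              nrow(x$usage), ncol(x$usage),
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}
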