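#' QC configuration
#'
#' Thresholds follow the common droplet scRNA-seq convention and are applied
#' as strict inequalities in the stated direction: cells with fewer than
#' `min_umi` total counts, fewer than `min_genes` detected genes, or more than
#' `max_mito_frac` mitochondrial count fraction are removed; genes detected in
#' fewer than `min_cells_per_gene` cells (after the cell filter) are removed.
#' For T-cell compartments the conventional mitochondrial cutoff is 0.20
#' rather than 0.30; pass `max_mito_frac = 0.20` for those analyses.
#'
#' @param min_umi Minimum total UMI count per cell (default 400).
#' @param min_genes Minimum detected genes per cell (default 200).
#' @param max_mito_frac Maximum mitochondrial count fraction (default 0.30).
#' @param min_cells_per_gene Minimum cells detecting a gene (default 3).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_umi = 400, min_genes = 200, max_mito_frac = 0.30,
                      min_cells_per_gene = 3) {
  stopifnot(min_umi >= 0, min_genes >= 0, min_cells_per_gene >= 0,
            max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_mito_frac = max_mito_frac,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_config")
}

#' Quality-control filtering of cells then genes
#'
#' A cell is removed when its total UMI count is below `min_umi`, its number
#' of detected genes is below `min_genes`, or its mitochondrial fraction
#' (mitochondrial counts / total counts) exceeds `max_mito_frac` — all strict
#' inequalities, so a cell at exactly 400 UMIs, 200 genes and 30.0% mito is
#' retained. Genes detected in fewer than `min_cells_per_gene` of the
#' *retained* cells are then removed (the gene filter runs after the cell
#' filter).
#'
#' @param matrix A [cell_matrix()] of raw counts.
#' @param genes Gene annotation tibble with `gene_id` and `is_mito`
#'   (see [read_genes()]); only genes present in the matrix are consulted.
#' @param cfg A [qc_config()].
#' @return A list with `matrix` (the filtered `cell_matrix`), `cells` (a
#'   tibble of per-cell QC metrics and `qc_pass` flags for *all* input cells),
#'   and `dropped_genes` (character vector).
#' @export
qc_filter <- function(matrix, genes, cfg = qc_config()) {
  stopifnot(inherits(matrix, "cell_matrix"), inherits(cfg, "qc_config"))
  .require_cols(genes, c("gene_id", "is_mito"), "gene table")
  counts <- matrix$counts
  missing <- setdiff(colnames(counts), genes$gene_id)
  if (length(missing)) {
    abort(paste0("genes without annotation (is_mito undefined): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  is_mito <- genes$is_mito[match(colnames(counts), genes$gene_id)]
  total <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- if (any(is_mito)) Matrix::rowSums(counts[, is_mito, drop = FALSE]) else
    rep(0, nrow(counts))
  mito_frac <- ifelse(total > 0, mito / total, 1)
  pass <- total >= cfg$min_umi & n_genes >= cfg$min_genes &
    mito_frac <= cfg$max_mito_frac
  cells <- tibble(cell_id = rownames(counts), total_umi = as.numeric(total),
                  n_genes = as.numeric(n_genes), mito_frac = mito_frac,
                  qc_pass = pass)
  if (!any(pass)) {
    abort(sprintf(
      "all %d cells removed by QC (%d below %d UMIs, %d below %d genes, %d above %.0f%% mito)",
      nrow(counts), sum(total < cfg$min_umi), cfg$min_umi,
      sum(n_genes < cfg$min_genes), cfg$min_genes,
      sum(mito_frac > cfg$max_mito_frac), 100 * cfg$max_mito_frac),
      class = "clonotrace_empty_result_error")
  }
  kept <- counts[pass, , drop = FALSE]
  gene_keep <- Matrix::colSums(kept > 0) >= cfg$min_cells_per_gene
  out <- matrix
  out$counts <- kept[, gene_keep, drop = FALSE]
  if (!is.null(matrix$lognorm)) {
    out$lognorm <- matrix$lognorm[pass, gene_keep, drop = FALSE]
  }
  list(matrix = out, cells = cells,
       dropped_genes = colnames(counts)[!gene_keep])
}

#' Library-size log2 normalization
#'
#' Adds the log-normalized layer: `lognorm[c, g] = log2(1 + scale *
#' counts[c, g] / total_counts[c])`. Zero counts stay exactly zero and the
#' transform is invariant to multiplying all counts of a cell by a constant.
#'
#' @param matrix A [cell_matrix()] (QC-filtered, so no zero-total cells).
#' @param scale Scale factor (default 10000 counts per cell).
#' @return The `cell_matrix` with its `lognorm` layer populated.
#' @export
normalize_log2 <- function(matrix, scale = 10000) {
  stopifnot(inherits(matrix, "cell_matrix"), scale > 0)
  total <- Matrix::rowSums(matrix$counts)
  if (any(total == 0)) {
    abort("cells with zero total counts cannot be normalized; run qc_filter first",
          class = "clonotrace_validation_error")
  }
  ln <- as.matrix(matrix$counts / total * scale)
  ln <- log2(1 + ln)
  dimnames(ln) <- dimnames(matrix$counts)
  matrix$lognorm <- ln
  matrix
}
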