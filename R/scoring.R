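#' Cellular detection rate
#'
#' The CDR of a gene in a group of cells is the fraction of those cells with
#' a nonzero count — equivalently one minus the dropout rate.
#'
#' @param matrix A [cell_matrix()].
#' @param cells Character vector of cell ids defining the group (non-empty).
#' @param genes Character vector of gene ids; `NULL` for all genes.
#' @return A tibble with columns `gene_id` and `cdr`.
#' @export
cdr <- function(matrix, cells, genes = NULL) {
  stopifnot(inherits(matrix, "cell_matrix"))
  if (!length(cells)) {
    abort("cdr needs a non-empty cell subset", class = "clonotrace_validation_error")
  }
  sub <- subset_cells(matrix, cells = cells, genes = genes)
  tibble(gene_id = colnames(sub$counts),
         cdr = as.numeric(Matrix::colSums(sub$counts > 0)) / nrow(sub$counts))
}

#' Per-cell gene-set score from z-scored expression
#'
#' Each set gene's log-normalized expression is z-scored across cells (genes
#' with zero variance contribute 0 for every cell); the score is the mean of
#' these standardized values over the set genes present in the matrix.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param gene_set Character vector of gene ids.
#' @return A tibble with columns `cell_id` and `score`.
#' @export
geneset_score_z <- function(matrix, gene_set) {
  ln <- .lognorm_or_stop(matrix, "geneset_score_z")
  present <- intersect(gene_set, colnames(ln))
  if (!length(present)) {
    abort(paste0("no gene of the set is present in the matrix; missing: ",
                 paste(head(setdiff(gene_set, colnames(ln)), 10), collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  x <- ln[, present, drop = FALSE]
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  z <- sweep(x, 2, mu, "-")
  z <- sweep(z, 2, ifelse(s > 0, s, Inf), "/")  # sd = 0 -> contributes 0
  tibble(cell_id = rownames(ln), score = unname(rowMeans(z)))
}

#' Per-cell gene-set score with bin-matched control genes
#'
#' Reimplementation of the expression-bin matched-control module score: all
#' genes are ranked by mean log-normalized expression and cut into `n_bins`
#' equal-size bins; for each set gene, `n_ctrl` control genes are sampled with
#' replacement from that gene's bin; the per-cell score is the mean expression
#' of the set genes minus the mean expression of the pooled control draws.
#' Deterministic given `seed`.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param gene_set Character vector of gene ids; absent genes are dropped
#'   with a warning (erroring when none remain).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return A tibble with columns `cell_id` and `score`.
#' @export
geneset_score_binned <- function(matrix, gene_set, n_bins = 24, n_ctrl = 100,
                                 seed = 1L) {
  ln <- .lognorm_or_stop(matrix, "geneset_score_binned")
  if (ncol(ln) < n_bins) {
    abort("matrix has fewer genes than bins", class = "clonotrace_validation_error")
  }
  absent <- setdiff(gene_set, colnames(ln))
  if (length(absent)) {
    warn(paste0("dropping set genes absent from matrix: ",
                paste(head(absent, 10), collapse = ", ")))
  }
  present <- intersect(gene_set, colnames(ln))
  if (!length(present)) {
    abort("no gene of the set is present in the matrix",
          class = "clonotrace_validation_error")
  }
  mean_expr <- colMeans(ln)
  # equal-size bins over the expression ranking (ties broken by gene order)
  ord_rank <- rank(mean_expr, ties.method = "first")
  bin <- ceiling(ord_rank / length(mean_expr) * n_bins)
  names(bin) <- colnames(ln)
  ctrl_draws <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      members <- colnames(ln)[bin == bin[[g]]]
      sample(members, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- rowMeans(ln[, present, drop = FALSE])
  ctrl_mean <- rowMeans(ln[, ctrl_draws, drop = FALSE])
  tibble(cell_id = rownames(ln), score = unname(set_mean - ctrl_mean))
}

#' Tumor score from malignant and non-malignant signatures
#'
#' The tumor score of a cell is its bin-matched malignant-signature score
#' minus its non-malignant-signature score; swapping the two sets negates it.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param malignant_set,nonmalignant_set Character vectors of gene ids.
#' @param seed Integer seed (shared by both [geneset_score_binned()] calls).
#' @inheritParams geneset_score_binned
#' @return A tibble with columns `cell_id` and `score`.
#' @export
tumor_score <- function(matrix, malignant_set, nonmalignant_set,
                        n_bins = 24, n_ctrl = 100, seed = 1L) {
  mal <- geneset_score_binned(matrix, malignant_set, n_bins, n_ctrl, seed)
  nonmal <- geneset_score_binned(matrix, nonmalignant_set, n_bins, n_ctrl, seed)
  tibble(cell_id = mal$cell_id, score = mal$score - nonmal$score)
}

#' Wilcoxon rank-sum differential expression with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum test per gene on the log-normalized layer
#' (exact for small tie-free samples, tie-corrected normal approximation
#' otherwise, as in [stats::wilcox.test()]). The fold change is the
#' difference of group means in log2-normalized space: `log2fc =
#' mean_lognorm(a) - mean_lognorm(b)`. Bonferroni multiplies by the number of
#' genes actually tested.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param cells_a,cells_b Disjoint character vectors of cell ids (each >= 2).
#' @param cells_out Optional cell ids of an "outside" population; when given,
#'   a `cdr_out` column reports each gene's detection rate there (used by
#'   [intersect_degs()]).
#' @return A tibble with columns `gene_id`, `log2fc`, `p_value`, `p_adj`,
#'   `cdr_in` (detection rate in `cells_a`) and `cdr_out` (NA when
#'   `cells_out` is absent).
#' @export
deg_wilcoxon <- function(matrix, cells_a, cells_b, cells_out = NULL) {
  ln <- .lognorm_or_stop(matrix, "deg_wilcoxon")
  if (length(intersect(cells_a, cells_b))) {
    abort("cells_a and cells_b overlap", class = "clonotrace_validation_error")
  }
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    abort("both groups need at least 2 cells", class = "clonotrace_validation_error")
  }
  a <- ln[cells_a, , drop = FALSE]
  b <- ln[cells_b, , drop = FALSE]
  p <- vapply(seq_len(ncol(ln)), function(j) {
    suppressWarnings(wilcox.test(a[, j], b[, j], alternative = "two.sided")$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # all-constant gene carries no evidence
  cdr_in <- as.numeric(colMeans(a > 0))
  cdr_out <- if (is.null(cells_out)) rep(NA_real_, ncol(ln)) else
    cdr(matrix, cells_out)$cdr
  tibble(gene_id = colnames(ln),
         log2fc = unname(colMeans(a) - colMeans(b)),
         p_value = p,
         p_adj = pmin(1, p * ncol(ln)),
         cdr_in = cdr_in,
         cdr_out = cdr_out)
}

#' Intersect single-cell and bulk DEG lists under the standard filters
#'
#' Bulk DEGs are kept when `p_adj < bulk_p_max` and `|log2fc| > lfc_min`;
#' single-cell DEGs when `p_adj < sc_p_max`, `|log2fc| > lfc_min` and
#' `cdr_out < cdr_out_max` (detection rate outside the focal compartment).
#' All comparisons are strict, so a single-cell gene at `p_adj = 1e-9` or
#' `cdr_out = 0.05` exactly is excluded.
#'
#' @param sc_degs Tibble from [deg_wilcoxon()] including `cdr_out`.
#' @param bulk_degs Tibble with `gene_id`, `log2fc`, `p_adj`.
#' @param sc_p_max Single-cell adjusted-p cutoff (default 1e-10).
#' @param bulk_p_max Bulk adjusted-p cutoff (default 0.05).
#' @param lfc_min Absolute log2 fold-change cutoff (default 1).
#' @param cdr_out_max Outside-detection-rate cutoff (default 0.05).
#' @return Character vector of gene ids surviving both filters (may be empty).
#' @export
intersect_degs <- function(sc_degs, bulk_degs, sc_p_max = 1e-10,
                           bulk_p_max = 0.05, lfc_min = 1, cdr_out_max = 0.05) {
  .require_cols(sc_degs, c("gene_id", "log2fc", "p_adj", "cdr_out"), "sc DEG table")
  .require_cols(bulk_degs, c("gene_id", "log2fc", "p_adj"), "bulk DEG table")
  sc_keep <- sc_degs$gene_id[sc_degs$p_adj < sc_p_max &
                             abs(sc_degs$log2fc) > lfc_min &
                             sc_degs$cdr_out < cdr_out_max]
  bulk_keep <- bulk_degs$gene_id[bulk_degs$p_adj < bulk_p_max &
                                 abs(bulk_degs$log2fc) > lfc_min]
  intersect(sc_keep, bulk_keep)
}

#' Combined Spearman correlation across datasets
#'
#' For each candidate gene, the Spearman rank correlation with the target
#' gene is computed independently in each dataset (average ranks for ties)
#' and the per-dataset coefficients are multiplied into a combined
#' coefficient, so its sign is the product of the per-dataset signs.
#' Candidates whose outside-compartment detection rate is `>= cdr_out_max`
#' are dropped before any correlation. A dataset in which the target or
#' candidate is constant yields an undefined coefficient; that candidate's
#' combined value is reported as `NA`, not 0.
#'
#' @param target_gene Gene id of the anchor gene (present in every dataset).
#' @param candidate_genes Character vector of candidate gene ids.
#' @param datasets Named list (>= 2) of samples x genes expression tables
#'   (matrix or data frame with gene-named columns).
#' @param cdr_out Optional named numeric vector of outside-compartment
#'   detection rates for the candidates; `NULL` skips the filter.
#' @param cdr_out_max Strict upper bound for `cdr_out` (default 0.05).
#' @return A tibble with one row per retained candidate: per-dataset
#'   coefficients (`r_<dataset>`) and `combined`.
#' @export
combined_correlation <- function(target_gene, candidate_genes, datasets,
                                 cdr_out = NULL, cdr_out_max = 0.05) {
  if (length(datasets) < 2) {
    abort("need at least two datasets", class = "clonotrace_validation_error")
  }
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  datasets <- lapply(datasets, function(d) as.matrix(as.data.frame(d)))
  for (nm in names(datasets)) {
    if (!target_gene %in% colnames(datasets[[nm]])) {
      abort(paste0("target gene absent from dataset ", nm),
            class = "clonotrace_validation_error")
    }
  }
  if (!is.null(cdr_out)) {
    candidate_genes <- candidate_genes[
      candidate_genes %in% names(cdr_out) & cdr_out[candidate_genes] < cdr_out_max]
  }
  rows <- lapply(candidate_genes, function(g) {
    rs <- vapply(datasets, function(d) {
      if (!g %in% colnames(d)) return(NA_real_)
      x <- d[, target_gene]; y <- d[, g]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      suppressWarnings(cor(x, y, method = "spearman"))
    }, numeric(1))
    c(rs, combined = if (anyNA(rs)) NA_real_ else prod(rs))
  })
  out <- as_tibble(do.call(rbind, rows))
  names(out) <- c(paste0("r_", names(datasets)), "combined")
  dplyr::bind_cols(tibble(gene_id = candidate_genes), out)
}
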