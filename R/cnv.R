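#' Reference-relative smoothed copy-number profile
#'
#' Estimates per-cell copy-number deviations from expression, relative to a
#' reference population (typically immune plus stromal cells):
#'
#' 1. genes are placed in genomic order (chromosome, then start);
#' 2. each gene's log-normalized expression is centered by its reference-cell
#'    mean;
#' 3. residuals are clipped to `± clip * max(reference sd, sd_floor)`;
#' 4. a moving average over `window` genes is taken within each chromosome
#'    (the window is truncated near chromosome edges so every average spans
#'    at least half a window; chromosome boundaries are never smoothed
#'    across);
#' 5. each cell is re-centered by its own median;
#' 6. each gene column is re-centered by its reference-cell mean, so the
#'    reference profile averages to zero per gene.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param genes Gene annotation tibble (`gene_id`, `chromosome`, `start`);
#'   genes absent from it are dropped from the profile.
#' @param reference_cells Character vector of >= 20 reference cell ids.
#' @param window Odd number of genes in the moving average (default 101);
#'   shrinks with a warning when it exceeds the smallest chromosome.
#' @param clip Clipping multiple of the reference standard deviation
#'   (default 3).
#' @param sd_floor Lower floor for the reference sd used in clipping
#'   (default 0.1).
#' @return An object of class `cnv_profile`: list with `values` (cells x
#'   ordered-genes matrix of deviations), `genes` (ordered annotation),
#'   `reference_cells`, `window`, `clip`.
#' @export
infer_cnv <- function(matrix, genes, reference_cells, window = 101, clip = 3,
                      sd_floor = 0.1) {
  ln <- .lognorm_or_stop(matrix, "infer_cnv")
  .require_cols(genes, c("gene_id", "chromosome", "start"), "gene table")
  if (window %% 2 != 1 || window < 1) {
    abort("window must be an odd positive integer", class = "clonotrace_validation_error")
  }
  if (length(reference_cells) < 20) {
    abort("need at least 20 reference cells", class = "clonotrace_validation_error")
  }
  missing_ref <- setdiff(reference_cells, rownames(ln))
  if (length(missing_ref)) {
    abort(paste0("reference cells absent from matrix: ",
                 paste(head(missing_ref, 5), collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  genes <- genes |>
    filter(.data$gene_id %in% colnames(ln)) |>
    arrange(.data$chromosome, .data$start, .data$gene_id)
  if (!nrow(genes)) {
    abort("no matrix gene has coordinates", class = "clonotrace_validation_error")
  }
  x <- ln[, genes$gene_id, drop = FALSE]
  ref <- x[reference_cells, , drop = FALSE]
  ref_mean <- colMeans(ref)
  ref_sd <- pmax(apply(ref, 2, sd), sd_floor)
  resid <- sweep(x, 2, ref_mean, "-")
  lim <- clip * ref_sd
  resid <- sweep(resid, 2, lim, function(a, b) pmin(a, b))
  resid <- sweep(resid, 2, -lim, function(a, b) pmax(a, b))

  chrom_sizes <- table(genes$chromosome)
  if (window > min(chrom_sizes)) {
    warn(sprintf("window %d exceeds smallest chromosome (%d genes); shrinking",
                 window, min(chrom_sizes)))
  }
  smooth <- resid
  for (chr in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == chr)
    m <- length(idx)
    w <- min(window, if (m %% 2 == 1) m else m - 1)
    half <- (w - 1) / 2
    block <- resid[, idx, drop = FALSE]
    cs <- cbind(0, t(apply(block, 1, cumsum)))
    for (i in seq_len(m)) {
      # window truncated at chromosome edges, never smoothed across them
      h_lo <- min(half, i - 1)
      h_hi <- min(half, m - i)
      smooth[, idx[i]] <- (cs[, i + h_hi + 1] - cs[, i - h_lo]) /
        (h_lo + h_hi + 1)
    }
  }
  smooth <- sweep(smooth, 1, apply(smooth, 1, median), "-")
  smooth <- sweep(smooth, 2, colMeans(smooth[reference_cells, , drop = FALSE]), "-")
  structure(list(values = smooth, genes = genes,
                 reference_cells = reference_cells,
                 window = window, clip = clip),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d ordered genes (window %d, clip %g, %d reference cells)\n",
              nrow(x$values), ncol(x$values), x$window, x$clip,
              length(x$reference_cells)))
  invisible(x)
}

#' Per-cell CNV burden score
#'
#' The CNV score of a cell is the mean of its squared copy-number deviations
#' across the genome; it is zero iff every deviation is zero and is invariant
#' to gene order.
#'
#' @param profile A `cnv_profile` from [infer_cnv()].
#' @return A tibble with columns `cell_id` and `cnv_score` (each >= 0).
#' @export
cnv_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (any(!is.finite(profile$values))) {
    abort("profile contains non-finite values", class = "clonotrace_validation_error")
  }
  tibble(cell_id = rownames(profile$values),
         cnv_score = unname(rowMeans(profile$values^2)))
}
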