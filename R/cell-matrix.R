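#' Construct a cell-by-gene count container
#'
#' `cell_matrix` is the package's expression container: a sparse cells x genes
#' integer count matrix plus, after [normalize_log2()], a log-normalized layer
#' of identical shape. Cell and gene identifiers are the dimnames and must be
#' unique; joins against cell metadata are by exact string match on `cell_id`.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   cells in rows, genes in columns, with unique dimnames.
#' @param lognorm Optional log-normalized layer of identical shape, as
#'   produced by [normalize_log2()].
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `lognorm` (a dense matrix or `NULL`).
#' @export
#' @examples
#' m <- cell_matrix(matrix(c(0, 2, 1, 0, 3, 0), nrow = 2,
#'                  dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' dim(m)
cell_matrix <- function(counts, lognorm = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    abort("counts must be non-negative integers", class = "clonotrace_validation_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry cell and gene identifiers as dimnames",
          class = "clonotrace_validation_error")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("cell and gene identifiers must be unique",
          class = "clonotrace_validation_error")
  }
  if (!is.null(lognorm)) {
    lognorm <- as.matrix(lognorm)
    if (!identical(dim(lognorm), dim(counts))) {
      abort("lognorm layer must match counts shape",
            class = "clonotrace_validation_error")
    }
    dimnames(lognorm) <- dimnames(counts)
  }
  structure(list(counts = counts, lognorm = lognorm), class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @export
dimnames.cell_matrix <- function(x) dimnames(x$counts)

#' Cell and gene identifiers of a cell_matrix
#' @param x A [cell_matrix()].
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset a cell_matrix by cell and/or gene identifiers
#'
#' @param x A [cell_matrix()].
#' @param cells,genes Character vectors of identifiers (or logical/integer
#'   indices); `NULL` keeps everything.
#' @return A `cell_matrix` restricted to the requested cells and genes; the
#'   lognorm layer, when present, is subset identically.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  cells <- cells %||% rownames(x$counts)
  genes <- genes %||% colnames(x$counts)
  if (is.character(cells)) {
    missing <- setdiff(cells, rownames(x$counts))
    if (length(missing)) {
      abort(paste0("unknown cell ids: ", paste(head(missing, 5), collapse = ", ")),
            class = "clonotrace_validation_error")
    }
  }
  if (is.character(genes)) {
    missing <- setdiff(genes, colnames(x$counts))
    if (length(missing)) {
      abort(paste0("unknown gene ids: ", paste(head(missing, 5), collapse = ", ")),
            class = "clonotrace_validation_error")
    }
  }
  out <- x
  out$counts <- x$counts[cells, genes, drop = FALSE]
  if (!is.null(x$lognorm)) out$lognorm <- x$lognorm[cells, genes, drop = FALSE]
  out
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes; %s stored counts; lognorm: %s\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              if (is.null(x$lognorm)) "absent" else "present"))
  invisible(x)
}

# lognorm layer or informative error
.lognorm_or_stop <- function(x, what) {
  if (is.null(x$lognorm)) {
    abort(paste0(what, " requires the log-normalized layer; run normalize_log2() first"),
          class = "clonotrace_validation_error")
  }
  x$lognorm
}
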