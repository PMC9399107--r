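#' Read a cell x gene count matrix
#'
#' Accepts either a MatrixMarket triplet directory (`matrix.mtx` plus
#' `barcodes.tsv` and `features.tsv`/`genes.tsv` sidecars, the 10x convention)
#' or a single dense TSV with cells in rows (first column `cell_id`, remaining
#' columns genes). Orientation of the MTX is auto-detected from the sidecar
#' lengths and normalized to cells x genes.
#'
#' @param path Directory containing the MTX triplet, a path to a `.mtx` file
#'   (sidecars are looked up next to it), or a dense `.tsv` file.
#' @return A [cell_matrix()] with integer counts.
#' @export
read_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) {
      abort(paste0("no matrix.mtx under ", path), class = "clonotrace_format_error")
    }
    return(.read_mtx_triplet(mtx))
  }
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "clonotrace_format_error")
  }
  if (grepl("\\.mtx$", path)) return(.read_mtx_triplet(path))
  .read_dense_tsv(path)
}

.read_sidecar <- function(path) {
  x <- readLines(path)
  # 10x features.tsv may carry extra columns; the first is the identifier
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

.read_mtx_triplet <- function(mtx_path) {
  dir <- dirname(mtx_path)
  barcodes_path <- file.path(dir, "barcodes.tsv")
  features_path <- file.path(dir, "features.tsv")
  if (!file.exists(features_path)) features_path <- file.path(dir, "genes.tsv")
  for (p in c(barcodes_path, features_path)) {
    if (!file.exists(p)) {
      abort(paste0("missing sidecar file: ", p), class = "clonotrace_format_error")
    }
  }
  if (file.size(mtx_path) == 0) {
    abort("empty matrix file", class = "clonotrace_format_error")
  }
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) abort(paste0("malformed MTX: ", conditionMessage(e)),
                                          class = "clonotrace_format_error"))
  barcodes <- .read_sidecar(barcodes_path)
  features <- .read_sidecar(features_path)
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # genes x cells on disk -> cells x genes
    dimnames(m) <- list(barcodes, features)
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    dimnames(m) <- list(barcodes, features)
  } else {
    abort(sprintf(
      "MTX dimensions %dx%d do not match sidecars (%d barcodes, %d features)",
      nrow(m), ncol(m), length(barcodes), length(features)),
      class = "clonotrace_format_error")
  }
  cell_matrix(m)
}

.read_dense_tsv <- function(path) {
  if (file.size(path) == 0) {
    abort("empty matrix file", class = "clonotrace_format_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) {
    abort("dense matrix TSV needs a cell_id column plus gene columns",
          class = "clonotrace_format_error")
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  cell_matrix(m)
}

.tissue_levels <- c("blood", "paratumor", "tumor")
.compartment_levels <- c("CD4", "CD8", "other")

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "clonotrace_schema_error")
  }
}

#' Read per-cell metadata
#'
#' Required columns: `cell_id`, `patient`, `tissue`, `cluster`. Optional:
#' `compartment` (one of CD4/CD8/other; defaults to "other"), `qc_pass`
#' (defaults TRUE) and `tcr_doublet` (defaults FALSE). `tissue` must be one of
#' blood, paratumor, tumor. Unknown columns are preserved.
#'
#' @param path TSV file with a header row.
#' @return A tibble of validated cell metadata.
#' @export
read_cells <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .require_cols(df, c("cell_id", "patient", "tissue", "cluster"), "cell table")
  df <- mutate(df, across(c("cell_id", "patient", "tissue", "cluster"), as.character))
  bad <- setdiff(unique(df$tissue), .tissue_levels)
  if (length(bad)) {
    abort(paste0("tissue values outside {blood, paratumor, tumor}: ",
                 paste(bad, collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  if (anyDuplicated(df$cell_id)) {
    abort("duplicate cell_id in cell table", class = "clonotrace_validation_error")
  }
  if (!"compartment" %in% names(df)) df$compartment <- "other"
  bad <- setdiff(unique(df$compartment), .compartment_levels)
  if (length(bad)) {
    abort(paste0("compartment values outside {CD4, CD8, other}: ",
                 paste(bad, collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  if (!"qc_pass" %in% names(df)) df$qc_pass <- TRUE
  if (!"tcr_doublet" %in% names(df)) df$tcr_doublet <- FALSE
  df$qc_pass <- as.logical(df$qc_pass)
  df$tcr_doublet <- as.logical(df$tcr_doublet)
  as_tibble(df)
}

#' Read gene annotation
#'
#' Required columns: `gene_id`, `chromosome`, `start`, `is_mito`. The
#' (chromosome, start) pair defines the genomic order used by [infer_cnv()].
#'
#' @param path TSV file with a header row.
#' @return A tibble of gene coordinates with a logical `is_mito` flag.
#' @export
read_genes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .require_cols(df, c("gene_id", "chromosome", "start", "is_mito"), "gene table")
  df <- mutate(df,
               gene_id = as.character(.data$gene_id),
               chromosome = as.character(.data$chromosome),
               start = as.integer(.data$start),
               is_mito = as.logical(.data$is_mito))
  if (anyDuplicated(df$gene_id)) {
    abort("duplicate gene_id in gene table", class = "clonotrace_validation_error")
  }
  as_tibble(df)
}

#' Read a 10x-style TCR contig annotation table
#'
#' Expects the `filtered_contig_annotations.csv` column convention: `barcode`,
#' `chain`, `v_gene`, `d_gene`, `j_gene`, `cdr3` (amino acid), `cdr3_nt`,
#' `productive`. Rows whose chain is not TRA/TRB (e.g. "Multi") are dropped.
#' `productive` accepts logicals or the 10x "True"/"None" strings.
#'
#' @param path CSV file with a header row.
#' @return A tibble with columns `cell_id`, `chain`, `v_gene`, `d_gene`,
#'   `j_gene`, `cdr3_nt`, `cdr3_aa`, `productive`.
#' @export
read_contigs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_cols(df, c("barcode", "chain", "cdr3_nt", "productive"), "contig table")
  for (col in c("v_gene", "d_gene", "j_gene", "cdr3")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  out <- tibble(
    cell_id = as.character(df$barcode),
    chain = as.character(df$chain),
    v_gene = as.character(df$v_gene),
    d_gene = as.character(df$d_gene),
    j_gene = as.character(df$j_gene),
    cdr3_nt = as.character(df$cdr3_nt),
    cdr3_aa = as.character(df$cdr3),
    productive = .parse_10x_logical(df$productive)
  )
  out <- filter(out, .data$chain %in% c("TRA", "TRB"))
  bad <- out$productive & (is.na(out$cdr3_nt) | out$cdr3_nt == "" | out$cdr3_nt == "None")
  if (any(bad)) {
    abort("productive contig with empty cdr3_nt", class = "clonotrace_validation_error")
  }
  out
}

.parse_10x_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated preserving first occurrence; empty sets are rejected.
#'
#' @param path GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file", class = "clonotrace_format_error")
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(parts) {
    if (length(parts) < 3) {
      abort("GMT line with fewer than 3 fields", class = "clonotrace_format_error")
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      abort(paste0("empty gene set: ", parts[[1]]), class = "clonotrace_format_error")
    }
    list(name = parts[[1]], genes = genes)
  })
  setNames(lapply(sets, `[[`, "genes"), vapply(sets, `[[`, character(1), "name"))
}

#' Read a ligand-receptor pair table
#'
#' Required columns `ligand` and `receptor`; an optional `pair_id` column is
#' generated as `ligand_receptor` when absent. Multi-subunit complexes are
#' expected to be pre-expanded to one row per subunit pair.
#'
#' @param path CSV file with a header row.
#' @return A tibble with columns `pair_id`, `ligand`, `receptor`.
#' @export
read_lr <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_cols(df, c("ligand", "receptor"), "ligand-receptor table")
  out <- tibble(
    pair_id = if ("pair_id" %in% names(df)) as.character(df$pair_id)
              else paste(df$ligand, df$receptor, sep = "_"),
    ligand = as.character(df$ligand),
    receptor = as.character(df$receptor)
  )
  if (anyDuplicated(out$pair_id)) {
    abort("duplicate pair_id in ligand-receptor table",
          class = "clonotrace_validation_error")
  }
  out
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), UTF-8, tab separator, `.` decimal
#' mark; numeric values are written with enough digits that re-reading
#' reproduces them to at least 12 significant digits. Matrices are written
#' with their row names in a leading `row_id` column.
#'
#' @param result A data frame, tibble, or matrix.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_table <- function(result, path) {
  if (is.matrix(result)) {
    df <- as_tibble(result, rownames = "row_id")
  } else {
    df <- as_tibble(result)
  }
  old <- options(scipen = 0)
  on.exit(options(old))
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- NA_character_
    out
  })
  tryCatch(
    readr::write_tsv(df, path, na = "NA", progress = FALSE),
    error = function(e) abort(paste0("cannot write ", path, ": ",
                                     conditionMessage(e)),
                              class = "clonotrace_io_error")
  )
  invisible(result)
}

#' Write a cell_matrix as an MTX triplet
#'
#' Emits `matrix.mtx` (genes x cells, the 10x on-disk convention),
#' `barcodes.tsv` and `features.tsv` under `dir`.
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  invisible(dir)
}
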