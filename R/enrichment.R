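#' Ro/e: observed over expected tissue enrichment
#'
#' For a two-way contingency table of cell counts (clusters x tissues by
#' default), the expected count of each entry is `row total * column total /
#' n` and Ro/e is observed/expected. Entries whose row or column total is
#' zero are undefined and reported as `NA`, not 0. The expected-count-
#' weighted mean of Ro/e within any row (or column) is exactly 1.
#'
#' @param cells Tibble of cell metadata.
#' @param row_key,col_key Column names defining rows and columns of the
#'   table (defaults `"cluster"` and `"tissue"`).
#' @return An object of class `roe_table`: list with integer matrix
#'   `observed`, numeric matrices `expected` and `roe`, and the key names.
#' @export
roe <- function(cells, row_key = "cluster", col_key = "tissue") {
  .require_cols(cells, c(row_key, col_key), "cell table")
  observed <- table(factor(cells[[row_key]]), factor(cells[[col_key]]))
  observed <- matrix(as.integer(observed), nrow = nrow(observed),
                     dimnames = dimnames(observed))
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    abort("Ro/e needs at least 2 rows and 2 columns",
          class = "clonotrace_validation_error")
  }
  rt <- rowSums(observed)
  ct <- colSums(observed)
  expected <- outer(rt, ct) / sum(observed)
  roe_mat <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(list(observed = observed, expected = expected, roe = roe_mat,
                 row_key = row_key, col_key = col_key),
            class = "roe_table")
}

#' @export
print.roe_table <- function(x, ...) {
  cat(sprintf("<roe_table> %s x %s (%d x %d)\n", x$row_key, x$col_key,
              nrow(x$roe), ncol(x$roe)))
  print(round(x$roe, 3))
  invisible(x)
}

#' Tissue-enriched sections of an Ro/e table
#'
#' Returns the (row, column) pairs whose Ro/e strictly exceeds `threshold`
#' (default 1, the enrichment convention). Undefined entries (zero margins)
#' are never returned.
#'
#' @param roe_table A `roe_table` from [roe()].
#' @param threshold Strict lower bound on Ro/e (default 1).
#' @return A tibble with the row key, column key, and `roe` columns.
#' @export
enriched_sections <- function(roe_table, threshold = 1.0) {
  stopifnot(inherits(roe_table, "roe_table"))
  long <- tidy(roe_table)
  out <- long[!is.na(long$roe) & long$roe > threshold, , drop = FALSE]
  out[, c(roe_table$row_key, roe_table$col_key, "roe")]
}
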