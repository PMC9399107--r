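#' Split cell subtypes into tissue-enriched sections
#'
#' Each (cluster, tissue) combination whose Ro/e strictly exceeds
#' `threshold` becomes an analysis "section" (e.g. `Fib_1@tumor`);
#' cells of non-enriched combinations are dropped.
#'
#' @param cells Cell metadata tibble with `cluster` and `tissue`.
#' @param roe_table Optional precomputed [roe()] table; computed from
#'   `cells` when `NULL`.
#' @param threshold Strict Ro/e lower bound (default 1).
#' @return The retained cells with an added `section` column
#'   (`cluster@tissue`).
#' @export
section_subtypes <- function(cells, roe_table = NULL, threshold = 1.0) {
  .require_cols(cells, c("cluster", "tissue"), "cell table")
  roe_table <- roe_table %||% roe(cells, "cluster", "tissue")
  keep <- enriched_sections(roe_table, threshold)
  if (!nrow(keep)) {
    abort("no (cluster, tissue) section exceeds the Ro/e threshold",
          class = "clonotrace_empty_result_error")
  }
  out <- inner_join(cells, keep[, c("cluster", "tissue")],
                    by = c("cluster", "tissue"))
  mutate(out, section = paste(.data$cluster, .data$tissue, sep = "@"))
}

#' Permutation test for ligand-receptor interactions
#'
#' For every patient, every ligand-receptor pair and every ordered pair of
#' sections (sender expressing the ligand, receiver the receptor), the
#' observed statistic is the mean of the ligand's mean log-normalized
#' expression over sender cells and the receptor's over receiver cells.
#' Sections with fewer than `min_cells` cells in a patient are excluded, and
#' a record is tested only when the ligand is detected in more than
#' `min_frac` of sender cells and the receptor in more than `min_frac` of
#' receiver cells (ineligible records are reported with `tested = FALSE`,
#' not p = 1). The null distribution is obtained by permuting section labels
#' across all of the patient's sectioned cells (section sizes preserved)
#' `n_perm` times; the empirical p-value uses the add-one pseudocount
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)`, so it is never 0.
#'
#' @param matrix A normalized [cell_matrix()].
#' @param sections Sectioned cell tibble from [section_subtypes()] with
#'   `cell_id`, `patient`, `section`.
#' @param lr_pairs Tibble from [read_lr()]; pairs whose genes are absent
#'   from the matrix are skipped with a warning.
#' @param min_cells Minimum cells per section per patient (default 20;
#'   a 19-cell section is excluded).
#' @param min_frac Strict minimum expressed fraction (default 0.30).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param include_self Also test sender = receiver sections (default FALSE).
#' @return A tibble of class `lr_records` with one row per (patient,
#'   pair, sender, receiver): `mean_stat`, `p_value` (NA when untested),
#'   `expressed_frac_ligand`, `expressed_frac_receptor`, `tested`.
#' @export
lr_test <- function(matrix, sections, lr_pairs, min_cells = 20,
                    min_frac = 0.30, n_perm = 1000, seed = 1L,
                    include_self = FALSE) {
  ln <- .lognorm_or_stop(matrix, "lr_test")
  .require_cols(sections, c("cell_id", "patient", "section"), "section table")
  .require_cols(lr_pairs, c("pair_id", "ligand", "receptor"), "pair table")
  genes_needed <- union(lr_pairs$ligand, lr_pairs$receptor)
  absent <- setdiff(genes_needed, colnames(ln))
  if (length(absent)) {
    warn(paste0("skipping pairs with genes absent from matrix: ",
                paste(head(absent, 10), collapse = ", ")))
    lr_pairs <- filter(lr_pairs, !.data$ligand %in% absent,
                       !.data$receptor %in% absent)
  }
  if (!nrow(lr_pairs)) {
    abort("no testable ligand-receptor pair", class = "clonotrace_validation_error")
  }
  genes <- union(lr_pairs$ligand, lr_pairs$receptor)
  out <- list()
  for (pat in sort(unique(sections$patient))) {
    pc <- filter(sections, .data$patient == pat,
                 .data$cell_id %in% rownames(ln))
    sizes <- table(pc$section)
    eligible <- names(sizes)[sizes >= min_cells]
    if (length(eligible) < 2) {
      inform(sprintf("patient %s: fewer than 2 eligible sections; skipped", pat))
      next
    }
    pc <- filter(pc, .data$section %in% eligible)
    x <- ln[pc$cell_id, genes, drop = FALSE]
    lab <- factor(pc$section, levels = eligible)
    group_means <- function(labels) {
      rowsum(x, labels) / as.vector(table(labels))   # sections x genes
    }
    m_obs <- group_means(lab)
    frac <- rowsum((x > 0) * 1, lab) / as.vector(table(lab))
    pairs_df <- tidyr::expand_grid(pair_idx = seq_len(nrow(lr_pairs)),
                                   sender = eligible, receiver = eligible)
    if (!include_self) pairs_df <- filter(pairs_df, .data$sender != .data$receiver)
    lig <- lr_pairs$ligand[pairs_df$pair_idx]
    rec <- lr_pairs$receptor[pairs_df$pair_idx]
    si <- match(pairs_df$sender, eligible)
    ri <- match(pairs_df$receiver, eligible)
    li <- cbind(si, match(lig, genes))
    rj <- cbind(ri, match(rec, genes))
    obs <- (m_obs[li] + m_obs[rj]) / 2
    f_l <- frac[cbind(si, match(lig, genes))]
    f_r <- frac[cbind(ri, match(rec, genes))]
    tested <- f_l > min_frac & f_r > min_frac
    exceed <- numeric(length(obs))
    withr::with_seed(seed, {
      for (k in seq_len(n_perm)) {
        mk <- group_means(sample(lab))
        exceed <- exceed + ((mk[li] + mk[rj]) / 2 >= obs)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
    out[[pat]] <- tibble(
      patient = pat,
      pair_id = lr_pairs$pair_id[pairs_df$pair_idx],
      sender = pairs_df$sender, receiver = pairs_df$receiver,
      mean_stat = obs,
      p_value = ifelse(tested, p, NA_real_),
      expressed_frac_ligand = f_l,
      expressed_frac_receptor = f_r,
      tested = tested)
  }
  if (!length(out)) {
    abort("no patient had 2 or more eligible sections",
          class = "clonotrace_empty_result_error")
  }
  res <- bind_rows(out)
  class(res) <- c("lr_records", class(res))
  res
}

#' Aggregate ligand-receptor records into a cross-patient network
#'
#' A (pair, sender, receiver) interaction counts as significant when its
#' empirical p-value is below `alpha` in at least one patient. Edges connect
#' unordered section pairs; the edge count is the number of distinct
#' significant (pair, direction) interactions, and `prop_patients` is the
#' fraction of patients in whom the section pair was testable that had at
#' least one significant interaction on the edge. Node weight is the total
#' number of significant interactions incident to the section.
#'
#' @param records An `lr_records` tibble from [lr_test()] (any number of
#'   patients).
#' @param alpha Significance cutoff (default 0.01, strict).
#' @return An object of class `lr_network`: list of tibbles `nodes`
#'   (`section`, `n_interactions`) and `edges` (`section_a`, `section_b`,
#'   `n_interactions`, `n_patients_significant`, `n_patients_eligible`,
#'   `prop_patients`).
#' @export
aggregate_network <- function(records, alpha = 0.01) {
  .require_cols(records, c("patient", "pair_id", "sender", "receiver",
                           "p_value", "tested"), "record table")
  rec <- records |>
    mutate(section_a = pmin(.data$sender, .data$receiver),
           section_b = pmax(.data$sender, .data$receiver),
           significant = .data$tested & !is.na(.data$p_value) &
             .data$p_value < alpha)
  edges <- rec |>
    group_by(.data$section_a, .data$section_b) |>
    summarise(
      n_interactions = dplyr::n_distinct(
        paste(.data$pair_id, .data$sender, .data$receiver)[.data$significant]),
      n_patients_eligible = dplyr::n_distinct(.data$patient[.data$tested]),
      n_patients_significant = dplyr::n_distinct(.data$patient[.data$significant]),
      .groups = "drop") |>
    filter(.data$n_patients_eligible > 0) |>
    mutate(prop_patients = .data$n_patients_significant /
             .data$n_patients_eligible)
  sig <- rec |>
    filter(.data$significant) |>
    distinct(.data$pair_id, .data$sender, .data$receiver)
  nodes <- tibble(section = union(rec$sender, rec$receiver)) |>
    dplyr::rowwise() |>
    mutate(n_interactions = sum(sig$sender == .data$section |
                                sig$receiver == .data$section)) |>
    ungroup() |>
    arrange(.data$section)
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "lr_network")
}

#' @export
print.lr_network <- function(x, ...) {
  cat(sprintf("<lr_network> %d sections, %d edges, alpha = %g\n",
              nrow(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}
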