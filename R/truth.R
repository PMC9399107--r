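#' Recovery metrics of pipeline outputs against planted ground truth
#'
#' Compares what the pipeline recovered from a [simulate_dataset()] output
#' with what the generator planted. All arguments other than `dataset` are
#' optional; metrics are computed for whatever is supplied.
#'
#' * `tumor_score_auc` — AUC of the tumor score separating planted tumor
#'   cells from planted normal epithelial cells.
#' * `cnv_auc`, `cnv_rank_p` — separation of per-cell CNV scores between
#'   planted CNV-bearing cells and reference cells (AUC and two-sided
#'   rank-sum p).
#' * `sharing_cor` — Pearson correlation between the planted cluster-pair
#'   overlap design and the recovered sharing-matrix entries (off-diagonal,
#'   within-compartment pairs).
#' * `migration_rank_cor` — Spearman correlation between the planted
#'   blood-tissue shared-clone fractions and the recovered Morisita-Horn
#'   indices across T-cell clusters.
#' * `lr_sensitivity`, `lr_fpr` — fraction of planted ligand-receptor
#'   interactions recovered at `alpha`, and fraction of tested non-planted
#'   records called significant.
#'
#' @param dataset A `synthetic_dataset`.
#' @param tumor_scores Tibble from [tumor_score()] (`cell_id`, `score`).
#' @param cnv_scores Tibble from [cnv_score()] (`cell_id`, `cnv_score`).
#' @param sharing A [sharing_matrix()].
#' @param mh Tibble from [morisita_horn()].
#' @param lr_records An `lr_records` tibble from [lr_test()].
#' @param alpha Significance cutoff for the LR metrics (default 0.01).
#' @return A tibble with columns `metric`, `value`, `n`.
#' @export
truth_report <- function(dataset, tumor_scores = NULL, cnv_scores = NULL,
                         sharing = NULL, mh = NULL, lr_records = NULL,
                         alpha = 0.01) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  truth <- dataset$truth
  cells <- dataset$cells
  rows <- list()
  add <- function(metric, value, n) {
    rows[[length(rows) + 1]] <<- tibble(metric = metric, value = value,
                                        n = as.integer(n))
  }

  if (!is.null(tumor_scores)) {
    .check_ids(tumor_scores$cell_id, cells$cell_id, "tumor_scores")
    df <- inner_join(tumor_scores, cells, by = "cell_id") |>
      filter(.data$cluster %in% c("Tumor", "NormalEpi"))
    add("tumor_score_auc",
        .auc(df$score[df$cluster == "Tumor"], df$score[df$cluster == "NormalEpi"]),
        nrow(df))
  }
  if (!is.null(cnv_scores)) {
    .check_ids(cnv_scores$cell_id, cells$cell_id, "cnv_scores")
    cnv_clusters <- unique(truth$config$cnv_segments$cluster)
    df <- inner_join(cnv_scores, cells, by = "cell_id")
    pos <- df$cnv_score[df$cluster %in% cnv_clusters]
    neg <- df$cnv_score[!df$cluster %in% cnv_clusters]
    if (length(pos) && length(neg)) {
      add("cnv_auc", .auc(pos, neg), length(pos) + length(neg))
      add("cnv_rank_p",
          suppressWarnings(wilcox.test(pos, neg)$p.value),
          length(pos) + length(neg))
    }
  }
  if (!is.null(sharing)) {
    design <- truth$sharing_design
    common <- intersect(rownames(design), rownames(sharing))
    planted <- recovered <- numeric(0)
    comp <- truth$config$clusters
    for (r in common) for (c in common) {
      if (r == c) next
      same_comp <- comp$compartment[comp$name == r] ==
        comp$compartment[comp$name == c]
      if (!same_comp) next
      if (is.na(sharing[r, c])) next
      planted <- c(planted, design[r, c])
      recovered <- c(recovered, sharing[r, c])
    }
    if (length(planted) >= 3 && sd(planted) > 0) {
      add("sharing_cor", cor(planted, recovered), length(planted))
    }
  }
  if (!is.null(mh)) {
    frac <- truth$blood_tissue_shared_frac
    df <- mh |> filter(.data$cluster %in% names(frac), !is.na(.data$index))
    if (nrow(df) >= 3 && sd(frac[df$cluster]) > 0) {
      add("migration_rank_cor",
          suppressWarnings(cor(frac[df$cluster], df$index, method = "spearman")),
          nrow(df))
    }
  }
  if (!is.null(lr_records)) {
    lt <- truth$lr_truth
    pairs <- truth$lr_pairs
    planted_key <- if (nrow(lt)) paste(
      pairs$pair_id[lt$pair_index],
      paste(lt$sender_cluster, lt$sender_tissue, sep = "@"),
      paste(lt$receiver_cluster, lt$receiver_tissue, sep = "@")) else character(0)
    # records sharing a planted pair and one planted endpoint are genuinely
    # elevated by the planted effect; they count for neither metric
    touched_key <- if (nrow(lt)) c(
      paste(pairs$pair_id[lt$pair_index], "s",
            paste(lt$sender_cluster, lt$sender_tissue, sep = "@")),
      paste(pairs$pair_id[lt$pair_index], "r",
            paste(lt$receiver_cluster, lt$receiver_tissue, sep = "@"))) else
      character(0)
    rec <- lr_records |>
      mutate(key = paste(.data$pair_id, .data$sender, .data$receiver),
             planted = .data$key %in% planted_key,
             touched = paste(.data$pair_id, "s", .data$sender) %in% touched_key |
               paste(.data$pair_id, "r", .data$receiver) %in% touched_key)
    tested <- filter(rec, .data$tested)
    if (any(tested$planted)) {
      add("lr_sensitivity",
          mean(tested$p_value[tested$planted] < alpha), sum(tested$planted))
    }
    null_rec <- filter(tested, !.data$touched)
    if (nrow(null_rec)) {
      add("lr_fpr", mean(null_rec$p_value < alpha), nrow(null_rec))
    }
  }
  if (!length(rows)) {
    abort("no pipeline output supplied", class = "clonotrace_validation_error")
  }
  bind_rows(rows)
}

.check_ids <- function(got, expected, what) {
  if (!length(intersect(got, expected))) {
    abort(paste0(what, ": cell ids do not match the dataset"),
          class = "clonotrace_validation_error")
  }
}

# rank-based AUC: P(score_pos > score_neg) + 0.5 P(tie)
.auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
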