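test_that("QC thresholds are strict inequalities on the stated boundaries", {
  # 3 diagnostic cells + 20 healthy fillers so the matrix survives filtering
  n_genes <- 260
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  genes <- toy_gene_annotation(gene_ids)
  genes$is_mito[n_genes] <- TRUE   # last gene mitochondrial
  build_cell <- function(umi, n_expressed, mito_counts) {
    v <- numeric(n_genes)
    base <- umi - mito_counts
    k <- n_expressed - (mito_counts > 0)
    v[seq_len(k)] <- c(rep(base %/% k, k - 1), base - (base %/% k) * (k - 1))
    v[n_genes] <- mito_counts
    v
  }
  rows <- rbind(
    low_umi = build_cell(399, 250, 0),          # 399 UMIs -> removed
    boundary = build_cell(400, 200, 120),       # 400/200/30.0% -> retained
    high_mito = build_cell(1000, 250, 301))     # 30.1% -> removed
  filler <- t(vapply(1:20, function(i) build_cell(2000, 250, 100),
                     numeric(n_genes)))
  counts <- rbind(rows, filler)
  rownames(counts) <- c("low_umi", "boundary", "high_mito",
                        sprintf("filler%02d", 1:20))
  colnames(counts) <- gene_ids
  res <- qc_filter(cell_matrix(counts), genes)
  flags <- setNames(res$cells$qc_pass, res$cells$cell_id)
  expect_false(flags[["low_umi"]])
  expect_true(flags[["boundary"]])
  expect_false(flags[["high_mito"]])
  expect_equal(flags[["boundary"]],
               sum(counts["boundary", genes$is_mito]) /
                 sum(counts["boundary", ]) <= 0.30)
})

test_that("gene filter runs after the cell filter", {
  # gene g is nonzero in 3 cells, but one of them fails QC -> 2 survivors -> drop
  n_genes <- 210
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  genes <- toy_gene_annotation(gene_ids)
  counts <- matrix(0L, 10, n_genes,
                   dimnames = list(sprintf("c%02d", 1:10), gene_ids))
  counts[, 1:205] <- 3L                       # everyone passes genes/UMIs
  counts[1, ] <- 0L                           # cell 1 fails QC entirely
  counts[, "g206"] <- 0L
  counts[c(1, 2, 3), "g206"] <- 5L            # 3 cells, one failing QC
  counts[c(1, 2, 3, 4), "g207"] <- 5L         # 3 cells after the cell filter
  res <- qc_filter(cell_matrix(counts), genes,
                   qc_config(min_umi = 100, min_genes = 100))
  expect_true("g206" %in% res$dropped_genes)
  expect_false("g207" %in% res$dropped_genes)
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  ds <- simulate_dataset(synthetic_config(n_patients = 1,
                                          cells_per_patient = 300), seed = 3)
  once <- qc_filter(ds$matrix, ds$genes)
  twice <- qc_filter(once$matrix, ds$genes)
  expect_identical(dim(twice$matrix), dim(once$matrix))
  expect_true(all(twice$cells$qc_pass))

  harsh <- qc_config(min_umi = 1e7)
  expect_error(qc_filter(ds$matrix, ds$genes, harsh),
               class = "clonotrace_empty_result_error")
})

test_that("normalize_log2 matches the closed form and its invariances", {
  counts <- matrix(c(10L, 0L, 4L, 6L), 2, 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  m <- normalize_log2(cell_matrix(counts), scale = 1)
  expect_equal(m$lognorm["c1", ], c(g1 = log2(2), g2 = 0))
  expect_equal(m$lognorm["c2", ],
               c(g1 = log2(1 + 0.4), g2 = log2(1 + 0.6)))

  # doubling a cell's counts leaves its lognorm row unchanged
  m2 <- normalize_log2(cell_matrix(counts * 2L), scale = 1)
  expect_equal(m2$lognorm, m$lognorm)

  # row sums of 2^lognorm - 1 equal the scale factor for every cell
  ds <- simulate_dataset(synthetic_config(n_patients = 1,
                                          cells_per_patient = 50), seed = 5)
  mn <- normalize_log2(ds$matrix, scale = 10000)
  expect_equal(rowSums(2^mn$lognorm - 1), rep(10000, nrow(mn$lognorm)),
               ignore_attr = TRUE)

  zero <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                 dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(normalize_log2(cell_matrix(zero)),
               class = "clonotrace_validation_error")
})

test_that("cdr counts expressing cells and matches brute force", {
  counts <- matrix(0L, 10, 3, dimnames = list(sprintf("c%02d", 1:10),
                                              c("g1", "g2", "g3")))
  counts[1:3, "g1"] <- 5L
  m <- cell_matrix(counts)
  res <- cdr(m, cells = rownames(counts))
  expect_equal(res$cdr[res$gene_id == "g1"], 0.3)
  expect_equal(res$cdr[res$gene_id == "g2"], 0)
  expect_error(cdr(m, cells = character(0)),
               class = "clonotrace_validation_error")

  # random sparse fixture vs dense brute-force count
  withr::with_seed(8, {
    rc <- matrix(rbinom(200, 2, 0.3), 20, 10,
                 dimnames = list(sprintf("c%02d", 1:20),
                                 sprintf("g%02d", 1:10)))
    sub <- sample(rownames(rc), 7)
    got <- cdr(cell_matrix(rc), cells = sub)
    want <- apply(rc[sub, ], 2, function(x) sum(x > 0) / length(x))
    expect_equal(got$cdr, unname(want))
  })
})

test_that("geneset_score_z standardizes per gene and averages over the set", {
  ln <- matrix(c(0, 2,        # g1 varies
                 1, 1),       # g2 constant
               2, 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
  m <- matrix_with_lognorm(ln)
  z1 <- geneset_score_z(m, "g2")
  expect_equal(z1$score, c(0, 0))               # sd = 0 contributes 0
  z2 <- geneset_score_z(m, "g1")
  expect_equal(z2$score, c(-1, 1) / sqrt(2))    # symmetric about 0
  expect_equal(sum(z2$score), 0)

  # brute-force oracle on a 20-cell, 5-gene set
  withr::with_seed(11, {
    big <- matrix(rnorm(20 * 8, 2), 20, 8,
                  dimnames = list(sprintf("c%02d", 1:20),
                                  sprintf("g%02d", 1:8)))
    set <- c("g01", "g03", "g05", "g06", "g08")
    got <- geneset_score_z(matrix_with_lognorm(big), set)
    want <- rowMeans(scale(big[, set]))
    expect_equal(got$score, unname(want))
  })

  # invariant to adding a constant to one gene across all cells
  shifted <- ln
  shifted[, "g1"] <- shifted[, "g1"] + 5
  expect_equal(geneset_score_z(matrix_with_lognorm(shifted), "g1")$score,
               z2$score)

  expect_error(geneset_score_z(m, c("nope1", "nope2")),
               class = "clonotrace_validation_error")
})

test_that("binned-control score is seeded, unbiased under self-control", {
  withr::with_seed(13, {
    ln <- matrix(rnorm(50 * 200, 1, 0.5), 50, 200,
                 dimnames = list(sprintf("c%02d", 1:50),
                                 sprintf("g%03d", 1:200)))
  })
  m <- matrix_with_lognorm(ln)
  all_genes <- colnames(ln)
  s <- geneset_score_binned(m, all_genes, seed = 4)
  expect_lt(max(abs(s$score)), 0.05)            # set == its own control
  expect_identical(geneset_score_binned(m, all_genes, seed = 4)$score, s$score)

  # 2-bin, 4-gene toy: replicate the documented control draw by hand
  toy <- matrix(c(0, 0, 1, 1,
                  0, 1, 2, 3), 2, 4, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("g1", "g2", "g3", "g4")))
  tm <- matrix_with_lognorm(toy)
  got <- geneset_score_binned(tm, "g4", n_bins = 2, n_ctrl = 3, seed = 7)
  # oracle: bins by mean expression rank; g4 sits in the top bin {g3, g4}
  mean_expr <- colMeans(toy)
  bin <- ceiling(rank(mean_expr, ties.method = "first") / 4 * 2)
  members <- colnames(toy)[bin == bin[["g4"]]]
  draws <- withr::with_seed(7, sample(members, 3, replace = TRUE))
  want <- toy[, "g4"] - rowMeans(toy[, draws, drop = FALSE])
  expect_equal(got$score, unname(want))

  expect_warning(geneset_score_binned(m, c(all_genes[1], "absent"), seed = 1),
                 "absent")
})

test_that("tumor score is the difference of binned scores", {
  withr::with_seed(17, {
    ln <- matrix(rnorm(30 * 100, 1, 0.5), 30, 100,
                 dimnames = list(sprintf("c%02d", 1:30),
                                 sprintf("g%03d", 1:100)))
  })
  m <- matrix_with_lognorm(ln)
  setA <- colnames(ln)[1:10]
  setB <- colnames(ln)[51:60]
  expect_equal(tumor_score(m, setA, setA, seed = 2)$score, rep(0, 30))
  ab <- tumor_score(m, setA, setB, seed = 2)$score
  ba <- tumor_score(m, setB, setA, seed = 2)$score
  expect_equal(ab, -ba)
})

test_that("planted tumor cells score above normal cells (AUC > 0.9)", {
  ds <- simulate_dataset(synthetic_config(), seed = 19)
  m <- normalize_log2(qc_filter(ds$matrix, ds$genes)$matrix)
  ts <- tumor_score(m, ds$gene_sets$malignant, ds$gene_sets$nonmalignant,
                    seed = 19)
  df <- dplyr::inner_join(ts, ds$cells, by = "cell_id")
  df <- df[df$cluster %in% c("Tumor", "NormalEpi"), ]
  df <- df[seq_len(min(400, nrow(df))), ]
  pos <- df$score[df$cluster == "Tumor"]
  neg <- df$score[df$cluster == "NormalEpi"]
  auc <- mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
  expect_gt(auc, 0.9)
})

test_that("deg_wilcoxon: exactness, identical groups, Bonferroni", {
  # exact small-sample case equals exhaustive enumeration over C(6,3)
  ln <- matrix(c(5, 6, 7, 1, 2, 3,
                 1, 1, 1, 1, 1, 1), 6, 2,
               dimnames = list(sprintf("c%d", 1:6), c("g1", "g2")))
  m <- matrix_with_lognorm(ln)
  res <- deg_wilcoxon(m, c("c1", "c2", "c3"), c("c4", "c5", "c6"))
  combos <- combn(6, 3)
  vals <- ln[, "g1"]
  stat <- function(idx) sum(rank(vals)[idx])
  obs <- stat(1:3)
  null_stats <- apply(combos, 2, stat)
  exact_p <- mean(abs(null_stats - mean(null_stats)) >=
                  abs(obs - mean(null_stats)))
  expect_equal(res$p_value[res$gene_id == "g1"], exact_p)
  expect_equal(res$log2fc[res$gene_id == "g1"], 6 - 2)
  expect_equal(res$p_adj, pmin(1, res$p_value * 2))

  # groups with identical value multisets: p = 1, log2fc = 0
  ln2 <- matrix(rep(c(1, 2, 3), 2), 6, 1,
                dimnames = list(sprintf("c%d", 1:6), "g1"))
  res2 <- deg_wilcoxon(matrix_with_lognorm(ln2), c("c1", "c2", "c3"),
                       c("c4", "c5", "c6"))
  expect_equal(res2$log2fc, 0)
  expect_gt(res2$p_value, 0.99)

  expect_error(deg_wilcoxon(m, c("c1", "c2"), c("c2", "c3")),
               class = "clonotrace_validation_error")
  expect_equal(pmin(1, 0.02 * 100), 1)  # documented Bonferroni saturation
})

test_that("DEG intersection applies the strict published filters", {
  sc <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    log2fc = c(2, 2, 0.5, -2, 2, 2),
    p_adj = c(1e-12, 1e-9, 1e-12, 1e-12, 1e-12, 1e-12),
    cdr_out = c(0.01, 0.01, 0.01, 0.01, 0.05, 0.01))
  bulk <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    log2fc = c(1.5, 1.5, 1.5, -1.5, 1.5, 0.2),
    p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  # g1: passes everything; g2: sc p_adj 1e-9 not < 1e-10; g3: |lfc| too low;
  # g4: passes (negative fold change); g5: cdr_out at the 0.05 boundary;
  # g6: bulk |lfc| too low
  expect_setequal(intersect_degs(sc, bulk), c("g1", "g4"))
})

test_that("combined correlation multiplies per-dataset Spearman coefficients", {
  withr::with_seed(23, {
    mk <- function() {
      d <- matrix(rnorm(8 * 4), 8, 4,
                  dimnames = list(NULL, c("t", "a", "b", "c")))
      d
    }
    ds <- list(x = mk(), y = mk(), z = mk())
  })
  res <- combined_correlation("t", c("a", "b", "c"), ds)
  # brute-force Spearman: rank then Pearson, average ranks for ties
  brute <- function(d, g) cor(rank(d[, "t"]), rank(d[, g]))
  for (g in c("a", "b", "c")) {
    row <- res[res$gene_id == g, ]
    expect_equal(row$r_x, brute(ds$x, g))
    expect_equal(row$combined, brute(ds$x, g) * brute(ds$y, g) * brute(ds$z, g))
    expect_equal(sign(row$combined),
                 sign(row$r_x) * sign(row$r_y) * sign(row$r_z))
  }

  # candidate identical to target everywhere -> combined exactly 1
  ds_id <- lapply(ds, function(d) {d[, "a"] <- d[, "t"]; d})
  expect_equal(combined_correlation("t", "a", ds_id)$combined, 1)

  # constant target -> NA (missing), not zero
  ds_const <- ds
  ds_const$x[, "t"] <- 1
  expect_true(is.na(combined_correlation("t", "a", ds_const)$combined))

  # CDR pre-filter drops candidates at/above the threshold
  res2 <- combined_correlation("t", c("a", "b"), ds,
                               cdr_out = c(a = 0.01, b = 0.05))
  expect_identical(res2$gene_id, "a")
})
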