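test_that("identical TCR sequences merge within but not across patients", {
  contigs <- dplyr::bind_rows(
    make_contigs(c("x1", "x1"), c("TRA", "TRB"), c("AAA", "CCC")),
    make_contigs(c("x2", "x2"), c("TRA", "TRB"), c("AAA", "CCC")),
    make_contigs(c("y1", "y1"), c("TRA", "TRB"), c("AAA", "CCC")))
  cells <- make_cells(c("x1", "x2", "y1"), patient = c("P1", "P1", "P2"))
  ct <- assign_clonotypes(contigs, cells)
  expect_equal(nrow(ct), 3)
  expect_equal(dplyr::n_distinct(ct$clonotype_id), 2)
  expect_equal(sort(unique(ct$clone_size[ct$patient == "P1"])), 2)
  expect_equal(ct$clone_size[ct$patient == "P2"], 1)
})

test_that("cells without productive TRB are excluded; contig order ignored", {
  contigs <- dplyr::bind_rows(
    make_contigs("a", "TRA", "AAA"),                        # TRA only -> out
    make_contigs(c("b", "b"), c("TRA", "TRB"), c("GGG", "TTT")),
    make_contigs("c", "TRB", "TTT"))
  cells <- make_cells(c("a", "b", "c"))
  ct <- assign_clonotypes(contigs, cells)
  expect_setequal(ct$cell_id, c("b", "c"))
  # b carries TRA+TRB, c carries the same TRB alone -> different multisets
  expect_equal(dplyr::n_distinct(ct$clonotype_id), 2)

  shuffled <- contigs[rev(seq_len(nrow(contigs))), ]
  ct2 <- assign_clonotypes(shuffled, cells)
  expect_equal(dplyr::arrange(ct2, cell_id)$clonotype_id,
               dplyr::arrange(ct, cell_id)$clonotype_id)

  expect_warning(
    assign_clonotypes(make_contigs(c("b", "b", "zz", "zz"),
                                   c("TRA", "TRB", "TRA", "TRB"),
                                   c("G", "T", "A", "C")), cells),
    "absent")
})

test_that("planted clonotype sizes are recovered exactly", {
  sizes <- c(20, 8, 2)
  cell_ids <- sprintf("c%02d", 1:30)
  grp <- rep(1:3, sizes)
  contigs <- dplyr::bind_rows(
    make_contigs(cell_ids, "TRA", paste0("A", grp)),
    make_contigs(cell_ids, "TRB", paste0("B", grp)))
  ct <- assign_clonotypes(contigs, make_cells(cell_ids))
  got <- ct |> dplyr::distinct(clonotype_id, clone_size) |>
    dplyr::pull(clone_size)
  expect_equal(sort(got, decreasing = TRUE), sizes)
})

test_that("doublet flag requires strictly more than two chains of one type", {
  contigs <- dplyr::bind_rows(
    make_contigs(rep("two_tra", 3), c("TRA", "TRA", "TRB"), c("A", "B", "C")),
    make_contigs(rep("three_trb", 3), c("TRB", "TRB", "TRB"), c("D", "E", "F")),
    make_contigs("unproductive", "TRB", "G", productive = FALSE))
  flags <- flag_tcr_doublets(contigs)
  f <- setNames(flags$tcr_doublet, flags$cell_id)
  expect_false(f[["two_tra"]])
  expect_true(f[["three_trb"]])
  expect_false(f[["unproductive"]])   # unproductive chains are not counted
})

test_that("expansion score counts cells in clonal clonotypes", {
  mk <- function(sizes, cluster = "C1") {
    n <- sum(sizes)
    tibble::tibble(cell_id = sprintf("%s_%d", cluster, 1:n), patient = "P1",
                   cluster = cluster, tissue = "tumor", compartment = "CD8",
                   clonotype_id = paste0(cluster, "_ct", rep(seq_along(sizes), sizes)),
                   clone_size = rep(sizes, sizes))
  }
  expect_equal(expansion_score(mk(rep(1, 5)))$expansion_score, 0)
  expect_equal(expansion_score(mk(10))$expansion_score, 1)
  expect_equal(expansion_score(mk(c(3, 2, 1, 1, 1, 1, 1)))$expansion_score, 0.5)
  expect_error(expansion_score(mk(1)[0, ]), class = "clonotrace_validation_error")
})

test_that("Morisita-Horn hand cases and brute-force enumeration agree", {
  # {a:1} vs {a:1, b:1} -> 2 * (1 * 0.5) / (1 + 0.25 + 0.25) = 2/3
  expect_equal(morisita_horn_index(c(a = 1), c(a = 1, b = 1)), 2 / 3)
  # identical relative compositions -> 1 (after scaling one side)
  expect_equal(morisita_horn_index(c(a = 2, b = 4), c(a = 1, b = 2)), 1)
  # disjoint repertoires -> 0
  expect_equal(morisita_horn_index(c(a = 3), c(b = 2)), 0)

  # exhaustive oracle: all size vectors over <= 4 clonotypes, sizes <= 3
  ids <- c("c1", "c2", "c3", "c4")
  grid <- expand.grid(t1 = 0:3, t2 = 0:3, t3 = 0:3, t4 = 0:3,
                      b1 = 0:3, b2 = 0:3, b3 = 0:3, b4 = 0:3)
  grid <- grid[rowSums(grid[, 1:4]) > 0 & rowSums(grid[, 5:8]) > 0, ]
  withr::with_seed(43, grid <- grid[sample(nrow(grid), 800), ])
  for (i in seq_len(nrow(grid))) {
    t <- unlist(grid[i, 1:4]); names(t) <- ids
    b <- unlist(grid[i, 5:8]); names(b) <- ids
    T_i <- t / sum(t); B_i <- b / sum(b)
    oracle <- 2 * sum(T_i * B_i) / sum(T_i^2 + B_i^2)
    got <- morisita_horn_index(t[t > 0], b[b > 0])
    expect_equal(got, oracle, tolerance = 1e-12)
    # symmetry and scale invariance
    expect_equal(morisita_horn_index(b[b > 0], t[t > 0]), got,
                 tolerance = 1e-12)
    expect_equal(morisita_horn_index(3 * t[t > 0], b[b > 0]), got,
                 tolerance = 1e-12)
  }
})

test_that("per-cluster Morisita-Horn handles empty compartments as missing", {
  ct <- tibble::tibble(
    cell_id = sprintf("c%d", 1:7), patient = "P1",
    cluster = c(rep("C1", 4), rep("C2", 3)),
    tissue = c("blood", "tumor", "tumor", "blood", rep("tumor", 3)),
    compartment = "CD8",
    clonotype_id = c("k1", "k1", "k2", "k3", "k4", "k4", "k5"),
    clone_size = c(2, 2, 1, 1, 2, 2, 1))
  mh <- morisita_horn(ct)
  # C1 blood {k1:1, k3:1}, tissue {k1:1, k2:1}
  expect_equal(mh$index[mh$cluster == "C1"],
               morisita_horn_index(c(k1 = 1, k2 = 1), c(k1 = 1, k3 = 1)))
  expect_true(is.na(mh$index[mh$cluster == "C2"]))  # no blood cells
  expect_equal(mh$blood_total[mh$cluster == "C2"], 0)
})

test_that("sharing matrix fractions, limits, and monotonicity", {
  base <- tibble::tibble(
    cell_id = sprintf("c%d", 1:8), patient = "P1", compartment = "CD8",
    tissue = "tumor",
    cluster = c("A", "A", "A", "A", "B", "B", "B", "B"),
    clonotype_id = c("k1", "k1", "k2", "k2", "k3", "k3", "k4", "k4"),
    clone_size = 2)
  sm <- sharing_matrix(base)
  expect_equal(unclass(sm), matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  expect_identical(rownames(sm), c("A", "B"))

  spanning <- base
  spanning$cluster <- rep(c("A", "B"), 4)
  expect_true(all(unclass(sharing_matrix(spanning)) == 1))

  # adding a cell of k1 to cluster B can only increase sharing(A, B)
  grown <- dplyr::bind_rows(base, tibble::tibble(
    cell_id = "c9", patient = "P1", compartment = "CD8", tissue = "tumor",
    cluster = "B", clonotype_id = "k1", clone_size = 3))
  expect_gte(sharing_matrix(grown)["A", "B"], sm["A", "B"])

  # singletons drop out under clonal_only
  with_singleton <- dplyr::bind_rows(base, tibble::tibble(
    cell_id = "c10", patient = "P1", compartment = "CD8", tissue = "tumor",
    cluster = "C", clonotype_id = "k9", clone_size = 1))
  expect_true(is.na(sharing_matrix(with_singleton)["C", "A"]))
  expect_false(is.na(sharing_matrix(with_singleton, clonal_only = FALSE)["C", "A"]))
})

test_that("planted sharing chain is recovered from synthetic data", {
  ds <- simulate_dataset(synthetic_config(), seed = 47)
  ct <- assign_clonotypes(ds$contigs, ds$cells)
  sm <- sharing_matrix(ct)
  # the Tc17 -> exhausted edge was planted at 0.4 vs 0.05 background
  expect_gt(sm["CD8_Tc17", "CD8_Exh"] - sm["CD8_Tc17", "CD8_Eff"], 0.2)
  design <- ds$truth$sharing_design
  cd8 <- grep("^CD8", rownames(design), value = TRUE)
  planted <- design[cd8, cd8][upper.tri(design[cd8, cd8]) |
                              lower.tri(design[cd8, cd8])]
  recovered <- unclass(sm)[cd8, cd8][upper.tri(sm[cd8, cd8]) |
                                     lower.tri(sm[cd8, cd8])]
  expect_gt(cor(planted, recovered), 0.8)
})

test_that("aggregation test: confined clonotypes give statistic 1", {
  ct <- tibble::tibble(
    cell_id = sprintf("c%d", 1:40), patient = "P1", compartment = "CD8",
    tissue = "tumor",
    cluster = rep(c("A", "B"), each = 20),
    clonotype_id = rep(sprintf("k%d", 1:20), each = 2),
    clone_size = 2)
  at <- clonal_aggregation_test(ct, "CD8", seed = 5)
  expect_true(all(at$real_stats == 1))
  expect_equal(at$n_clonotypes, 20)
  expect_equal(length(at$real_stats), length(at$perm_stats))
  expect_true(all(at$perm_stats > 0 & at$perm_stats <= 1))
  g <- glance(at)
  expect_equal(g$p_value, at$p_value)

  expect_error(clonal_aggregation_test(ct[1:6, ], "CD8", seed = 1),
               class = "clonotrace_validation_error")
  one_cluster <- ct
  one_cluster$cluster <- "A"
  expect_error(clonal_aggregation_test(one_cluster, "CD8", seed = 1),
               class = "clonotrace_validation_error")
})

test_that("VDJ usage embedding matches an independent eigen-decomposition", {
  # 5 clusters with controlled usage; cluster E has a near-exclusive V gene
  withr::with_seed(51, {
    n_per <- 200
    clusters <- rep(c("A", "B", "C", "D", "E"), each = n_per)
    cell_ids <- sprintf("cell%04d", seq_along(clusters))
    vpool <- paste0("TRBV", 1:6)
    v <- character(length(clusters))
    for (cl in c("A", "B", "C", "D")) {
      idx <- clusters == cl
      w <- rep(1, 6); w[match(cl, c("A", "B", "C", "D"))] <- 2
      v[idx] <- sample(vpool, sum(idx), TRUE, prob = w / sum(w))
    }
    idx <- clusters == "E"
    v[idx] <- sample(c("TRBV9", vpool), sum(idx), TRUE,
                     prob = c(0.9, rep(0.1 / 6, 6)))
  })
  contigs <- make_contigs(cell_ids, "TRB", paste0("NT", seq_along(cell_ids)),
                          v_gene = v)
  cells <- make_cells(cell_ids, cluster = clusters)
  emb <- vdj_usage_embedding(contigs, cells, n_components = 3)

  # oracle: z-score the usage matrix, eigen-decompose its covariance
  usage <- emb$usage
  z <- scale(usage[, apply(usage, 2, sd) > 0])
  ev <- eigen(cov(z))
  k <- 3
  oracle_coords <- z %*% ev$vectors[, 1:k]
  got <- as.matrix(emb$coordinates[, -1])
  for (j in 1:k) {
    expect_equal(abs(got[, j]), abs(oracle_coords[, j]), ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  expect_equal(emb$explained_variance,
               (ev$values / sum(ev$values))[1:k], tolerance = 1e-8)

  # the skewed-usage cluster is farthest from the embedding centroid
  d <- sqrt(rowSums(got^2))
  expect_equal(emb$coordinates$cluster[which.max(d)], "E")

  # clusters with identical usage collapse to identical coordinates
  cells2 <- cells
  cells2$cluster[cells2$cluster == "B"] <- "A"   # merge to force identity
  contigs_dup <- dplyr::bind_rows(
    contigs,
    dplyr::mutate(contigs[clusters == "A" | clusters == "B", ],
                  cell_id = paste0(cell_id, "_dup")))
  cells_dup <- dplyr::bind_rows(
    cells2,
    dplyr::mutate(cells2[cells2$cluster == "A", ],
                  cell_id = paste0(cell_id, "_dup"), cluster = "Adup"))
  emb2 <- vdj_usage_embedding(contigs_dup, cells_dup, n_components = 2)
  ca <- as.numeric(emb2$coordinates[emb2$coordinates$cluster == "A", -1])
  cb <- as.numeric(emb2$coordinates[emb2$coordinates$cluster == "Adup", -1])
  expect_equal(ca, cb, tolerance = 1e-10)

  expect_error(vdj_usage_embedding(contigs, cells, n_components = 5),
               class = "clonotrace_validation_error")
})
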