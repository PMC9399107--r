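#' Configuration for the synthetic paired expression + TCR generator
#'
#' Describes a multi-patient, three-tissue, cluster-structured dataset with
#' negative-binomial counts, power-law clone sizes, planted cross-cluster
#' clonotype sharing, blood-tissue shared clones, contiguous copy-number
#' segments in designated clusters, skewed VDJ usage, and boosted
#' ligand-receptor pairs in designated tissue sections. All signal strengths
#' are the generator's study conditions; [synthetic_null_config()] switches
#' every planted effect off.
#'
#' @param n_patients Number of patients (default 3).
#' @param cells_per_patient Cells per patient (default 2000).
#' @param n_genes Number of genes (default 1000), split evenly over
#'   `n_chromosomes` autosomes plus a small chrM block of mitochondrial
#'   genes.
#' @param n_chromosomes Autosomes (default 5).
#' @param clusters Cluster design tibble: `name`, `compartment`
#'   (CD4/CD8/other), `frac` (expected cell fraction), `p_blood`,
#'   `p_paratumor`, `p_tumor` (tissue sampling probabilities). The default
#'   emulates a gastric-tumor atlas: tumor and normal epithelium, stromal
#'   cells, and CD4/CD8 T-cell states including blood effector,
#'   tissue-resident, Tc17, exhausted and MAIT-like clusters.
#' @param baseline_logmean,baseline_logsd Log-normal law for per-gene
#'   negative-binomial means (defaults log(0.5), 1.2).
#' @param dispersion Negative-binomial size parameter theta (default 2).
#' @param size_factor_sd Log-normal sd of per-cell library size factors
#'   (default 0.3).
#' @param n_mito_genes,mito_fraction Mitochondrial genes on chrM and their
#'   expected count fraction (defaults 10 and 0.05).
#' @param program_size,program_lfc Genes per cluster expression program and
#'   their log2 fold-change (defaults 30 and 1.5; 0 disables programs).
#' @param cnv_segments Tibble of planted copy-number events: `cluster`,
#'   `chromosome`, `start_index` (gene index within the chromosome),
#'   `n_genes`, `multiplier`. Default: one 150-gene 2x amplification on
#'   chr2 in the Tumor cluster.
#' @param clone_gamma,clone_max Discrete power-law clone-size law
#'   `P(k) ~ k^-gamma`, k = 1..`clone_max` (defaults 2.5 and 50).
#' @param sharing_design Square matrix over T-cell cluster names: the
#'   probability that a clonal clonotype homed in the row cluster spills one
#'   member cell into the column cluster. Default plants a
#'   resident -> Tc17 -> exhausted chain at 0.4 against a 0.05 background
#'   (within-compartment only).
#' @param blood_tissue_shared_frac Named vector over T-cell clusters: the
#'   probability that a clonal clonotype homed there spans blood and solid
#'   tissue by construction.
#' @param clonotype_null When TRUE, T-cell cluster labels are drawn i.i.d.
#'   per cell, independent of clonotype (exchangeable-label null).
#' @param n_lr_pairs Number of ligand-receptor pairs (default 20); their
#'   genes get a fixed moderate mean (`lr_gene_mu`) so detection fractions
#'   clear the 30% eligibility bar.
#' @param lr_gene_mu Baseline NB mean of ligand/receptor genes (default 1.5).
#' @param lr_truth Tibble of planted interactions: `pair_index`,
#'   `sender_cluster`, `sender_tissue`, `receiver_cluster`,
#'   `receiver_tissue`, `effect` (mean multiplier). Default plants two
#'   tumor-section interactions between the Tumor and Stromal clusters.
#' @param doublet_frac Fraction of T cells given a third TRB chain
#'   (default 0.005).
#' @param mait_cluster,mait_v_gene,mait_v_freq A cluster with near-exclusive
#'   usage of one TRAV gene (defaults CD8_MAIT / TRAV1-2 / 0.9), emulating
#'   the invariant MAIT alpha chain.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 3,
    cells_per_patient = 2000,
    n_genes = 1000,
    n_chromosomes = 5,
    clusters = NULL,
    baseline_logmean = log(0.5),
    baseline_logsd = 1.2,
    dispersion = 2,
    size_factor_sd = 0.3,
    n_mito_genes = 10,
    mito_fraction = 0.05,
    program_size = 30,
    program_lfc = 1.5,
    cnv_segments = NULL,
    clone_gamma = 2.5,
    clone_max = 50,
    sharing_design = NULL,
    blood_tissue_shared_frac = NULL,
    clonotype_null = FALSE,
    n_lr_pairs = 20,
    lr_gene_mu = 1.5,
    lr_truth = NULL,
    doublet_frac = 0.005,
    mait_cluster = "CD8_MAIT",
    mait_v_gene = "TRAV1-2",
    mait_v_freq = 0.9) {
  clusters <- clusters %||% tibble(
    name = c("Tumor", "NormalEpi", "Stromal", "CD4_Naive", "CD4_Treg",
             "CD8_Eff", "CD8_Resident", "CD8_Tc17", "CD8_Exh", "CD8_MAIT"),
    compartment = c("other", "other", "other", "CD4", "CD4",
                    "CD8", "CD8", "CD8", "CD8", "CD8"),
    frac = c(0.15, 0.10, 0.15, 0.10, 0.10, 0.10, 0.10, 0.07, 0.08, 0.05),
    p_blood = c(0, 0, 0.05, 0.75, 0.10, 0.70, 0.05, 0.05, 0.02, 0.40),
    p_paratumor = c(0.10, 0.85, 0.35, 0.15, 0.30, 0.15, 0.50, 0.50, 0.18, 0.30),
    p_tumor = c(0.90, 0.15, 0.60, 0.10, 0.60, 0.15, 0.45, 0.45, 0.80, 0.30))
  stopifnot(abs(sum(clusters$frac) - 1) < 1e-8,
            all(abs(clusters$p_blood + clusters$p_paratumor +
                      clusters$p_tumor - 1) < 1e-8))
  t_clusters <- clusters$name[clusters$compartment != "other"]
  if (is.null(sharing_design)) {
    sharing_design <- matrix(0, length(t_clusters), length(t_clusters),
                             dimnames = list(t_clusters, t_clusters))
    for (r in t_clusters) for (c in t_clusters) {
      if (r != c &&
          clusters$compartment[clusters$name == r] ==
          clusters$compartment[clusters$name == c]) {
        sharing_design[r, c] <- 0.05
      }
    }
    # differentiation chain resident -> Tc17 <-> exhausted; the entry edge is
    # directional so a clonotype's spill budget (clone size - 1) stays
    # feasible for the Tc17 hub
    if (all(c("CD8_Resident", "CD8_Tc17") %in% t_clusters)) {
      sharing_design["CD8_Resident", "CD8_Tc17"] <- 0.4
    }
    if (all(c("CD8_Tc17", "CD8_Exh") %in% t_clusters)) {
      sharing_design["CD8_Tc17", "CD8_Exh"] <- 0.4
      sharing_design["CD8_Exh", "CD8_Tc17"] <- 0.4
    }
  }
  blood_tissue_shared_frac <- blood_tissue_shared_frac %||% setNames(
    c(0.05, 0.05, 0.60, 0.30, 0.20, 0.10, 0.50),
    c("CD4_Naive", "CD4_Treg", "CD8_Eff", "CD8_Resident", "CD8_Tc17",
      "CD8_Exh", "CD8_MAIT"))[t_clusters]
  cnv_segments <- cnv_segments %||% tibble(
    cluster = "Tumor", chromosome = "chr2", start_index = 26L,
    n_genes = 150L, multiplier = 2)
  lr_truth <- lr_truth %||% tibble(
    pair_index = c(1L, 2L),
    sender_cluster = c("Tumor", "Stromal"),
    sender_tissue = c("tumor", "tumor"),
    receiver_cluster = c("Stromal", "Tumor"),
    receiver_tissue = c("tumor", "tumor"),
    effect = c(6, 6))
  stopifnot(all(sharing_design >= 0 & sharing_design <= 1),
            all(blood_tissue_shared_frac >= 0 & blood_tissue_shared_frac <= 1),
            all(cnv_segments$multiplier > 0), clone_gamma > 1, clone_max >= 1,
            n_genes %% n_chromosomes == 0)
  bad <- setdiff(c(cnv_segments$cluster, lr_truth$sender_cluster,
                   lr_truth$receiver_cluster), clusters$name)
  if (length(bad)) {
    abort(paste0("config references undefined clusters: ",
                 paste(bad, collapse = ", ")),
          class = "clonotrace_validation_error")
  }
  structure(list(
    n_patients = n_patients, cells_per_patient = cells_per_patient,
    n_genes = n_genes, n_chromosomes = n_chromosomes, clusters = clusters,
    baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
    dispersion = dispersion, size_factor_sd = size_factor_sd,
    n_mito_genes = n_mito_genes, mito_fraction = mito_fraction,
    program_size = program_size, program_lfc = program_lfc,
    cnv_segments = cnv_segments, clone_gamma = clone_gamma,
    clone_max = clone_max, sharing_design = sharing_design,
    blood_tissue_shared_frac = blood_tissue_shared_frac,
    clonotype_null = clonotype_null, n_lr_pairs = n_lr_pairs,
    lr_gene_mu = lr_gene_mu, lr_truth = lr_truth,
    doublet_frac = doublet_frac, mait_cluster = mait_cluster,
    mait_v_gene = mait_v_gene, mait_v_freq = mait_v_freq),
    class = "synthetic_config")
}

#' Null configuration: every planted effect switched off
#'
#' Uniform tissue probabilities, no expression programs, no CNV segments,
#' no clonotype-cluster association (labels i.i.d.), no forced blood-tissue
#' sharing, no ligand-receptor effects. Downstream tests on such data behave
#' as calibrated nulls.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_null_config <- function(...) {
  base <- synthetic_config()
  clusters <- base$clusters
  clusters$p_blood <- 1 / 3
  clusters$p_paratumor <- 1 / 3
  clusters$p_tumor <- 1 / 3
  t_clusters <- clusters$name[clusters$compartment != "other"]
  synthetic_config(
    clusters = clusters,
    program_lfc = 0,
    cnv_segments = base$cnv_segments[0, ],
    sharing_design = matrix(0, length(t_clusters), length(t_clusters),
                            dimnames = list(t_clusters, t_clusters)),
    blood_tissue_shared_frac = setNames(rep(0, length(t_clusters)), t_clusters),
    clonotype_null = TRUE,
    lr_truth = synthetic_config()$lr_truth[0, ],
    doublet_frac = 0,
    mait_v_freq = 1 / 10,
    ...)
}

# discrete power-law clone sizes summing exactly to n_cells
.draw_clone_sizes <- function(n_cells, gamma, max_size) {
  k <- seq_len(max_size)
  prob <- k^(-gamma)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, sample(k, max(16, n_cells), replace = TRUE, prob = prob))
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n_cells)
  sizes[sizes > 0]
}

.random_nt <- function(n, len_range = c(30, 45)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

.random_aa <- function(n, len = 13) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste0("CAS", paste(sample(aa, len - 4, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Generate a synthetic paired expression + TCR dataset
#'
#' Deterministic given `seed`. Returns in-memory domain objects plus a
#' ground-truth record; when `dir` is given, also writes the on-disk formats
#' the io module reads (MTX triplet, cell and gene TSVs, a 10x-style contig
#' CSV, a GMT of the planted signatures, and a ligand-receptor CSV).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return A list of class `synthetic_dataset`: `matrix` ([cell_matrix()]),
#'   `cells`, `genes`, `contigs`, `gene_sets`, `lr_pairs`, and `truth`
#'   (list with per-clonotype truth, program genes, CNV segment gene ids,
#'   the sharing design, blood-tissue sharing fractions, the LR truth and
#'   planted doublet cells).
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1L,
                             dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, .simulate_impl(config, dir))
}

.simulate_impl <- function(cfg, dir) {
  per_chrom <- cfg$n_genes / cfg$n_chromosomes
  genes <- tibble(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chromosome = rep(paste0("chr", seq_len(cfg$n_chromosomes)),
                     each = per_chrom),
    start = as.integer(rep(seq_len(per_chrom), cfg$n_chromosomes) * 100000L),
    is_mito = FALSE)
  if (cfg$n_mito_genes > 0) {
    mito <- tibble(
      gene_id = sprintf("mt%02d", seq_len(cfg$n_mito_genes)),
      chromosome = "chrM",
      start = as.integer(seq_len(cfg$n_mito_genes) * 1000L),
      is_mito = TRUE)
    genes <- bind_rows(genes, mito)
  }
  n_genes_all <- nrow(genes)
  mu <- rlnorm(n_genes_all, cfg$baseline_logmean, cfg$baseline_logsd)
  names(mu) <- genes$gene_id

  # ligand/receptor genes: fixed moderate mean so detection clears min_frac
  lr_gene_ids <- character(0)
  lr_pairs <- tibble(pair_id = character(), ligand = character(),
                     receptor = character())
  if (cfg$n_lr_pairs > 0) {
    lr_gene_ids <- genes$gene_id[seq_len(2 * cfg$n_lr_pairs)]
    mu[lr_gene_ids] <- cfg$lr_gene_mu
    lr_pairs <- tibble(
      pair_id = sprintf("LR%02d", seq_len(cfg$n_lr_pairs)),
      ligand = lr_gene_ids[2 * seq_len(cfg$n_lr_pairs) - 1],
      receptor = lr_gene_ids[2 * seq_len(cfg$n_lr_pairs)])
  }
  if (cfg$n_mito_genes > 0) {
    mu[genes$is_mito] <- cfg$mito_fraction / (1 - cfg$mito_fraction) *
      sum(mu[!genes$is_mito]) / cfg$n_mito_genes
  }

  # planted CNV segment gene spans (contiguous in genomic order)
  segs <- cfg$cnv_segments
  seg_genes <- lapply(seq_len(nrow(segs)), function(i) {
    chr_genes <- genes$gene_id[genes$chromosome == segs$chromosome[i]]
    chr_genes[seq(segs$start_index[i],
                  length.out = min(segs$n_genes[i],
                                   length(chr_genes) - segs$start_index[i] + 1))]
  })

  # cluster expression programs on genes free of other planted signals
  pool <- setdiff(genes$gene_id[!genes$is_mito],
                  c(lr_gene_ids, unlist(seg_genes)))
  program_genes <- list()
  if (cfg$program_size > 0) {
    per <- min(cfg$program_size, floor(length(pool) / nrow(cfg$clusters)))
    if (per < 1) {
      abort("gene pool too small for cluster programs",
            class = "clonotrace_validation_error")
    }
    if (per < cfg$program_size) {
      inform(sprintf("gene pool supports %d program genes per cluster", per))
    }
    for (i in seq_len(nrow(cfg$clusters))) {
      take <- seq_len(per)
      program_genes[[cfg$clusters$name[i]]] <- pool[take]
      pool <- pool[-take]
    }
  }

  # --- cells, clusters, tissues, clonotypes -------------------------------
  cl <- cfg$clusters
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  all_cells <- list()
  clonotype_truth <- list()
  contigs <- list()
  t_clusters <- cl$name[cl$compartment != "other"]
  # per-cluster V-gene usage: each T cluster mildly prefers one TRAV/TRBV,
  # the MAIT-like cluster uses its invariant TRAV almost exclusively
  trav <- c(cfg$mait_v_gene, paste0("TRAV", c(2:9, 12)))
  trbv <- paste0("TRBV", c(2, 4:9, 11, 12, 20))
  traj <- paste0("TRAJ", 1:8)
  trbj <- paste0("TRBJ", 1:8)
  trbd <- paste0("TRBD", 1:2)
  v_usage <- function(cluster_name, pool_genes, preferred) {
    w <- rep(1, length(pool_genes))
    if (cluster_name == cfg$mait_cluster && pool_genes[1] == cfg$mait_v_gene) {
      w <- rep((1 - cfg$mait_v_freq) / (length(pool_genes) - 1),
               length(pool_genes))
      w[1] <- cfg$mait_v_freq
    } else {
      w[preferred] <- 3
    }
    w / sum(w)
  }

  for (p_idx in seq_along(patients)) {
    pat <- patients[p_idx]
    n <- cfg$cells_per_patient
    cluster0 <- sample(cl$name, n, replace = TRUE, prob = cl$frac)
    comp0 <- cl$compartment[match(cluster0, cl$name)]
    cell_id <- sprintf("%s_cell%05d-1", pat, seq_len(n))
    cluster <- cluster0
    clono <- rep(NA_character_, n)
    ct_counter <- 0L
    for (comp in c("CD4", "CD8")) {
      idx <- which(comp0 == comp)
      if (!length(idx)) next
      comp_cl <- cl$name[cl$compartment == comp]
      comp_w <- cl$frac[cl$compartment == comp]
      sizes <- .draw_clone_sizes(length(idx), cfg$clone_gamma, cfg$clone_max)
      homes <- sample(comp_cl, length(sizes), replace = TRUE, prob = comp_w)
      pos <- idx
      for (k in seq_along(sizes)) {
        s <- sizes[k]
        members <- pos[seq_len(s)]
        pos <- pos[-seq_len(s)]
        ct_counter <- ct_counter + 1L
        cid <- sprintf("%s_true_ct%05d", pat, ct_counter)
        clono[members] <- cid
        if (cfg$clonotype_null) {
          cluster[members] <- sample(comp_cl, s, replace = TRUE, prob = comp_w)
        } else {
          cluster[members] <- homes[k]
          if (s >= 2) {
            spill_pool <- members[-1]
            # strong planted edges claim the limited spill budget first
            partners <- setdiff(comp_cl, homes[k])
            partners <- partners[order(-cfg$sharing_design[homes[k], partners],
                                       runif(length(partners)))]
            for (partner in partners) {
              if (!length(spill_pool)) break
              pr <- cfg$sharing_design[homes[k], partner]
              if (runif(1) < pr) {
                cluster[spill_pool[1]] <- partner
                spill_pool <- spill_pool[-1]
              }
            }
          }
        }
        clonotype_truth[[cid]] <- tibble(
          clonotype_id = cid, patient = pat, home_cluster = homes[k],
          size = s)
      }
    }
    # tissues from (possibly spilled) cluster; then force planted
    # blood <-> solid spanning for designated clonal clonotypes
    probs <- as.matrix(cl[, c("p_blood", "p_paratumor", "p_tumor")])
    rownames(probs) <- cl$name
    tissue <- vapply(seq_len(n), function(i) {
      sample(.tissue_levels, 1, prob = probs[cluster[i], ])
    }, character(1))
    if (!cfg$clonotype_null) {
      for (cid in unique(clono[!is.na(clono)])) {
        tr <- clonotype_truth[[cid]]
        if (tr$size < 2) next
        frac <- cfg$blood_tissue_shared_frac[tr$home_cluster]
        if (is.na(frac) || runif(1) >= frac) next
        members <- which(clono == cid)
        solid_p <- probs[tr$home_cluster, c("p_paratumor", "p_tumor")]
        if (sum(solid_p) == 0) solid_p <- c(0.5, 0.5)
        tissue[members[1]] <- "blood"
        tissue[members[2]] <- sample(c("paratumor", "tumor"), 1,
                                     prob = solid_p / sum(solid_p))
        clonotype_truth[[cid]]$forced_blood_tissue <- TRUE
      }
    }
    all_cells[[pat]] <- tibble(
      cell_id = cell_id, patient = pat, tissue = tissue, cluster = cluster,
      compartment = cl$compartment[match(cluster, cl$name)],
      true_clonotype = clono)

    # --- TCR contigs: one TRA + one TRB per clonotype -------------------
    cts <- unique(clono[!is.na(clono)])
    if (length(cts)) {
      home <- vapply(cts, function(cid) clonotype_truth[[cid]]$home_cluster,
                     character(1))
      pref_a <- (match(home, t_clusters) %% length(trav)) + 1
      pref_b <- (match(home, t_clusters) %% length(trbv)) + 1
      va <- vapply(seq_along(cts), function(k) {
        sample(trav, 1, prob = v_usage(home[k], trav, pref_a[k]))
      }, character(1))
      vb <- vapply(seq_along(cts), function(k) {
        sample(trbv, 1, prob = v_usage(home[k], trbv, pref_b[k]))
      }, character(1))
      chain_def <- tibble(
        true_clonotype = cts,
        va = va, ja = sample(traj, length(cts), replace = TRUE),
        vb = vb, jb = sample(trbj, length(cts), replace = TRUE),
        db = sample(trbd, length(cts), replace = TRUE),
        cdr3a_nt = .random_nt(length(cts)), cdr3a_aa = .random_aa(length(cts)),
        cdr3b_nt = .random_nt(length(cts)), cdr3b_aa = .random_aa(length(cts)))
      tcells <- all_cells[[pat]] |> filter(!is.na(.data$true_clonotype)) |>
        left_join(chain_def, by = "true_clonotype")
      contigs[[pat]] <- bind_rows(
        tibble(cell_id = tcells$cell_id, chain = "TRA", v_gene = tcells$va,
               d_gene = NA_character_, j_gene = tcells$ja,
               cdr3_nt = tcells$cdr3a_nt, cdr3_aa = tcells$cdr3a_aa,
               productive = TRUE),
        tibble(cell_id = tcells$cell_id, chain = "TRB", v_gene = tcells$vb,
               d_gene = tcells$db, j_gene = tcells$jb,
               cdr3_nt = tcells$cdr3b_nt, cdr3_aa = tcells$cdr3b_aa,
               productive = TRUE))
    }
  }
  cells <- bind_rows(all_cells)
  contigs <- bind_rows(contigs)
  clonotype_truth <- bind_rows(clonotype_truth)
  if (!"forced_blood_tissue" %in% names(clonotype_truth)) {
    clonotype_truth$forced_blood_tissue <- FALSE
  }
  clonotype_truth$forced_blood_tissue <-
    !is.na(clonotype_truth$forced_blood_tissue) &
    clonotype_truth$forced_blood_tissue

  # planted TCR doublets: a third TRB chain
  doublet_cells <- character(0)
  tcr_cells <- unique(contigs$cell_id)
  n_doublets <- floor(cfg$doublet_frac * length(tcr_cells))
  if (n_doublets > 0) {
    doublet_cells <- sample(tcr_cells, n_doublets)
    extra <- lapply(doublet_cells, function(cc) {
      tibble(cell_id = cc, chain = "TRB",
             v_gene = sample(trbv, 2, replace = TRUE),
             d_gene = sample(trbd, 2, replace = TRUE),
             j_gene = sample(trbj, 2, replace = TRUE),
             cdr3_nt = .random_nt(2), cdr3_aa = .random_aa(2),
             productive = TRUE)
    })
    contigs <- bind_rows(contigs, bind_rows(extra))
  }

  # --- expression ---------------------------------------------------------
  n_cells <- nrow(cells)
  size_factor <- rlnorm(n_cells, 0, cfg$size_factor_sd)
  mu_mat <- outer(size_factor, mu)
  dimnames(mu_mat) <- list(cells$cell_id, genes$gene_id)
  if (cfg$program_lfc != 0 && length(program_genes)) {
    for (nm in names(program_genes)) {
      rows <- cells$cluster == nm
      if (any(rows)) {
        mu_mat[rows, program_genes[[nm]]] <-
          mu_mat[rows, program_genes[[nm]]] * 2^cfg$program_lfc
      }
    }
  }
  for (i in seq_len(nrow(segs))) {
    rows <- cells$cluster == segs$cluster[i]
    if (any(rows)) {
      mu_mat[rows, seg_genes[[i]]] <- mu_mat[rows, seg_genes[[i]]] *
        segs$multiplier[i]
    }
  }
  for (i in seq_len(nrow(cfg$lr_truth))) {
    tr <- cfg$lr_truth[i, ]
    pair <- lr_pairs[tr$pair_index, ]
    send <- cells$cluster == tr$sender_cluster & cells$tissue == tr$sender_tissue
    recv <- cells$cluster == tr$receiver_cluster & cells$tissue == tr$receiver_tissue
    mu_mat[send, pair$ligand] <- mu_mat[send, pair$ligand] * tr$effect
    mu_mat[recv, pair$receptor] <- mu_mat[recv, pair$receptor] * tr$effect
  }
  counts <- matrix(rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                           size = cfg$dispersion),
                   nrow = n_cells, dimnames = dimnames(mu_mat))
  mat <- cell_matrix(counts)

  gene_sets <- list()
  if (length(program_genes)) {
    gene_sets <- list(
      malignant = program_genes[["Tumor"]],
      nonmalignant = program_genes[["NormalEpi"]],
      cytolytic = program_genes[["CD8_Eff"]],
      exhaustion = program_genes[["CD8_Exh"]])
    gene_sets <- gene_sets[!vapply(gene_sets, is.null, logical(1))]
  }

  truth <- list(
    config = cfg,
    clonotypes = clonotype_truth,
    cell_clonotype = cells[, c("cell_id", "true_clonotype")],
    program_genes = program_genes,
    cnv_segment_genes = setNames(seg_genes, segs$cluster),
    sharing_design = cfg$sharing_design,
    blood_tissue_shared_frac = cfg$blood_tissue_shared_frac,
    lr_truth = cfg$lr_truth,
    lr_pairs = lr_pairs,
    doublet_cells = doublet_cells)
  cells_out <- select(cells, -"true_clonotype")

  out <- structure(list(matrix = mat, cells = cells_out, genes = genes,
                        contigs = contigs, gene_sets = gene_sets,
                        lr_pairs = lr_pairs, truth = truth),
                   class = "synthetic_dataset")
  if (!is.null(dir)) .write_dataset(out, dir)
  out
}

.write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(ds$matrix, dir)
  readr::write_tsv(ds$cells, file.path(dir, "cells.tsv"), progress = FALSE)
  readr::write_tsv(ds$genes, file.path(dir, "genes.tsv"), progress = FALSE)
  contigs_10x <- ds$contigs |>
    rename(barcode = "cell_id", cdr3 = "cdr3_aa") |>
    mutate(productive = ifelse(.data$productive, "True", "False"))
  readr::write_csv(contigs_10x, file.path(dir, "filtered_contig_annotations.csv"),
                   progress = FALSE)
  gmt <- vapply(names(ds$gene_sets), function(nm) {
    paste(c(nm, "synthetic", ds$gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  readr::write_csv(ds$lr_pairs, file.path(dir, "lr_pairs.csv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d cells x %d genes, %d patients, %d contig rows\n",
              nrow(x$matrix$counts), ncol(x$matrix$counts),
              length(unique(x$cells$patient)), nrow(x$contigs)))
  invisible(x)
}
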