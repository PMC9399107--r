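# Small fixtures shared across test files; everything is built in code.

# 3-cell x 4-gene toy with 5 nonzero entries
toy_counts <- function() {
  m <- matrix(0L, 3, 4, dimnames = list(c("c1", "c2", "c3"),
                                        c("g1", "g2", "g3", "g4")))
  m["c1", "g1"] <- 2L
  m["c1", "g3"] <- 1L
  m["c2", "g2"] <- 5L
  m["c3", "g1"] <- 1L
  m["c3", "g4"] <- 3L
  m
}

toy_matrix <- function() cell_matrix(toy_counts())

# cell_matrix with an explicitly chosen lognorm layer (for tests that need
# exact expression values rather than the count-derived transform)
matrix_with_lognorm <- function(lognorm) {
  counts <- matrix(1L, nrow(lognorm), ncol(lognorm),
                   dimnames = dimnames(lognorm))
  m <- cell_matrix(counts)
  m$lognorm <- lognorm
  m
}

toy_gene_annotation <- function(gene_ids, per_chrom = length(gene_ids)) {
  n <- length(gene_ids)
  tibble::tibble(
    gene_id = gene_ids,
    chromosome = paste0("chr", rep(seq_len(ceiling(n / per_chrom)),
                                   each = per_chrom)[seq_len(n)]),
    start = as.integer(rep(seq_len(per_chrom), length.out = n) * 1000L),
    is_mito = FALSE)
}

# minimal contig tibble in the shape read_contigs() returns
make_contigs <- function(cell_id, chain, cdr3_nt, v_gene = NA_character_,
                         productive = TRUE) {
  tibble::tibble(
    cell_id = cell_id, chain = chain,
    v_gene = if (length(v_gene) == 1) rep(v_gene, length(cell_id)) else v_gene,
    d_gene = NA_character_, j_gene = NA_character_,
    cdr3_nt = cdr3_nt, cdr3_aa = toupper(substr(cdr3_nt, 1, 6)),
    productive = rep(productive, length.out = length(cell_id)))
}

make_cells <- function(cell_id, patient = "P1", tissue = "tumor",
                       cluster = "C1", compartment = "CD8") {
  tibble::tibble(cell_id = cell_id,
                 patient = rep(patient, length.out = length(cell_id)),
                 tissue = rep(tissue, length.out = length(cell_id)),
                 cluster = rep(cluster, length.out = length(cell_id)),
                 compartment = rep(compartment, length.out = length(cell_id)))
}

# low-noise, high-depth counts: lognorm values concentrate tightly, which is
# what the CNV null-profile property needs
dense_null_matrix <- function(n_cells, n_genes, seed = 1) {
  withr::with_seed(seed, {
    mu <- runif(n_genes, 50, 150)
    counts <- matrix(rnbinom(n_cells * n_genes,
                             mu = rep(mu, each = n_cells), size = 100),
                     nrow = n_cells,
                     dimnames = list(sprintf("cell%03d", seq_len(n_cells)),
                                     sprintf("g%04d", seq_len(n_genes))))
    normalize_log2(cell_matrix(counts))
  })
}
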