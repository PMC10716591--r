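# Shared fixtures, built in code. The default simulation is the package's
# reference study design: paired input/enrichment libraries, 3 batches with
# planted rank-2 structure, 5% of endogenous genes NAD-capped at 4-fold.

shared_sim <- simulate_dataset(sim_params(seed = 1))
shared_filtered <- filter_genes(shared_sim$dataset)$dataset
shared_gene_sets <- suppressWarnings(select_gene_sets(shared_filtered))

# tiny deterministic dataset for interface-level tests
make_toy_dataset <- function(n_genes = 6, n_pairs = 2, seed = 42) {
  set.seed(seed)
  sample_id <- as.vector(t(outer(paste0("P", seq_len(n_pairs)),
                                 c("in", "en"), paste, sep = "_")))
  samples <- data.frame(
    sample_id = sample_id,
    batch = rep("B1", 2 * n_pairs),
    assay = rep(c("input", "enrichment"), n_pairs),
    group = rep("G1", 2 * n_pairs),
    pair_id = rep(paste0("P", seq_len(n_pairs)), each = 2))
  counts <- matrix(rpois(n_genes * 2 * n_pairs, 50), n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)), sample_id))
  genes <- data.frame(gene_id = rownames(counts),
                      origin = "endogenous", biotype = "protein_coding")
  sn_dataset(counts, samples, genes)
}

# brute-force silhouette from the definition (independent of the package path)
brute_silhouette <- function(embedding, labels) {
  D <- as.matrix(dist(embedding))
  labels <- as.character(labels)
  vapply(seq_len(nrow(D)), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# brute-force adjusted Rand index from the contingency-table formula
brute_ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  (sum_ij - expected) / ((a + b) / 2 - expected)
}
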