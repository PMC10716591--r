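# Benchmarking diagnostics: variance explained by a covariate across leading
# PCs, per-gene batch ANOVA and Spearman associations, Rozeboom vector
# correlation, ARI of assay separation, Jensen-Shannon sample heterogeneity,
# and the two baseline normalizers used for comparison.

covariate_indicators <- function(covariate) {
  if (is.numeric(covariate)) return(matrix(covariate, ncol = 1))
  f <- droplevels(as.factor(covariate))
  if (nlevels(f) < 2) stop("covariate is constant")
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

#' Variance of a covariate explained by cumulative expression PCs
#'
#' For each `k`, the pooled R-squared of regressing the covariate's
#' (centered) indicator columns on expression PCs 1..k — the "fraction of
#' variance explained by batch" diagnostic. Non-decreasing in `k`.
#'
#' @param matrix Genes x samples log-scale matrix or `sn_normalized`.
#' @param covariate Categorical or numeric covariate over samples.
#' @param k_max Largest number of PCs (at most samples - 1).
#' @return data.frame with columns `k`, `r2`.
#' @export
pc_covariate_r2 <- function(matrix, covariate, k_max = 6) {
  values <- if (inherits(matrix, "sn_normalized")) matrix$values
            else as.matrix(matrix)
  n <- ncol(values)
  if (k_max > n - 1) stop("k_max must be at most samples - 1")
  Y <- covariate_indicators(covariate)
  Y <- sweep(Y, 2, colMeans(Y))
  sst <- sum(Y^2)
  if (sst < 1e-12) stop("covariate is constant")
  pcs <- expr_pcs(values, k_max)
  r2 <- vapply(seq_len(k_max), function(k) {
    X <- cbind(1, pcs[, seq_len(k), drop = FALSE])
    sse <- sum(vapply(seq_len(ncol(Y)), function(j)
      sum(stats::lm.fit(X, Y[, j])$residuals^2), numeric(1)))
    1 - sse / sst
  }, numeric(1))
  data.frame(k = seq_len(k_max), r2 = r2)
}

#' Count genes affected by batch (per-gene one-way ANOVA)
#'
#' @param matrix Genes x samples matrix (log scale) or `sn_normalized`.
#' @param batch Batch labels (>= 2 batches with >= 2 samples each).
#' @param p_threshold Significance cutoff (default 0.01).
#' @return Integer count of genes with ANOVA p below the threshold;
#'   zero-variance genes are skipped (attribute `"n_skipped"`).
#' @export
anova_batch_count <- function(matrix, batch, p_threshold = 0.01) {
  values <- if (inherits(matrix, "sn_normalized")) matrix$values
            else as.matrix(matrix)
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) < 2 || any(table(batch) < 2))
    stop("need >= 2 batches with >= 2 samples each")
  n_skip <- 0L
  count <- 0L
  for (g in seq_len(nrow(values))) {
    y <- values[g, ]
    if (stats::sd(y) < 1e-12) { n_skip <- n_skip + 1L; next }
    p <- tryCatch(stats::oneway.test(y ~ batch, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    if (!is.na(p) && p < p_threshold) count <- count + 1L
  }
  structure(count, n_skipped = n_skip)
}

#' Per-gene Spearman correlation with batch
#'
#' @param matrix Genes x samples matrix or `sn_normalized`.
#' @param batch Batch labels, coerced to a numeric encoding.
#' @return Named numeric vector of per-gene rho; constant genes are reported
#'   as 0 and flagged in the attribute `"constant_genes"`.
#' @export
gene_batch_spearman <- function(matrix, batch) {
  values <- if (inherits(matrix, "sn_normalized")) matrix$values
            else as.matrix(matrix)
  b <- if (is.numeric(batch)) batch else as.integer(droplevels(as.factor(batch)))
  rho <- apply(values, 1, function(y) {
    if (stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(y, b, method = "spearman")
  })
  const <- which(is.na(rho))
  rho[const] <- 0
  attr(rho, "constant_genes") <- names(const)
  rho
}

#' Rozeboom squared vector correlation
#'
#' `1 - prod(1 - rho_i^2)` over the canonical correlations between the
#' expression PC block and the covariate indicator block.
#'
#' @param pcs Samples x k matrix of expression PC scores.
#' @param covariate_matrix Samples x m matrix of covariate indicators (or a
#'   factor/vector, converted internally).
#' @return Scalar in `[0, 1]`.
#' @export
vector_correlation <- function(pcs, covariate_matrix) {
  X <- as.matrix(pcs)
  Y <- if (is.matrix(covariate_matrix) || is.data.frame(covariate_matrix))
    as.matrix(covariate_matrix) else covariate_indicators(covariate_matrix)
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  keep_x <- apply(X, 2, function(v) sum(v^2) > 1e-12)
  keep_y <- apply(Y, 2, function(v) sum(v^2) > 1e-12)
  if (!any(keep_x) || !any(keep_y)) stop("rank-0 input")
  cc <- stats::cancor(X[, keep_x, drop = FALSE], Y[, keep_y, drop = FALSE],
                      xcenter = FALSE, ycenter = FALSE)
  rho <- pmin(cc$cor, 1)
  1 - prod(1 - rho^2)
}

#' Assay separation by adjusted Rand index
#'
#' Clusters samples on the leading expression PCs with partitioning around
#' medoids (k = number of assay levels) and reports the ARI against the
#' assay labels.
#'
#' @param normalized `sn_normalized` or genes x samples matrix.
#' @param assay_labels Assay labels per sample.
#' @param n_pcs Number of PCs.
#' @return Scalar ARI.
#' @export
ari_separation <- function(normalized, assay_labels, n_pcs = 3) {
  lab <- droplevels(as.factor(assay_labels))
  if (nlevels(lab) < 2) stop("both assay levels must be present")
  pcs <- expr_pcs(normalized, n_pcs)
  cl <- cluster::pam(pcs, nlevels(lab), cluster.only = TRUE)
  mclust::adjustedRandIndex(cl, lab)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon distance of each sample to the centroid profile
#'
#' Profiles are normalized to probability distributions; the centroid is
#' their mean. `JSD(Pc, Pi) = H((Pc+Pi)/2) - (H(Pc)+H(Pi))/2` with Shannon
#' entropy in log base 2, and the distance is its square root, bounded in
#' `[0, 1]`.
#'
#' @param profiles Samples x genes non-negative matrix; if
#'   `shift_nonnegative` is TRUE (for signed modification levels) the global
#'   minimum is subtracted first.
#' @param shift_nonnegative Shift signed profiles to non-negative before
#'   normalizing?
#' @return Named numeric vector of per-sample distances.
#' @export
jensen_shannon_distance <- function(profiles, shift_nonnegative = FALSE) {
  P <- as.matrix(profiles)
  if (shift_nonnegative) P <- P - min(P)
  if (any(P < 0)) stop("profiles must be non-negative (or use shift_nonnegative)")
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("all-zero profile(s): ",
                         paste(rownames(P)[rs <= 0], collapse = ", "))
  P <- P / rs
  pc <- colMeans(P)
  d <- vapply(seq_len(nrow(P)), function(i) {
    pi <- P[i, ]
    jsd <- shannon_entropy((pc + pi) / 2) -
      (shannon_entropy(pc) + shannon_entropy(pi)) / 2
    sqrt(max(jsd, 0))
  }, numeric(1))
  stats::setNames(d, rownames(P))
}

#' Scaling-only baseline normalizer for paired enrichment data
#'
#' Input libraries are scaled by DESeq median-of-ratios factors computed on
#' input counts; each enrichment library is scaled by a summary (mean, or
#' median) of the per-gene fold changes `F = en / in_norm` over the top
#' fraction of genes ranked by enrichment counts, where `in_norm` is the
#' paired, median-of-ratios-normalized input.
#'
#' @param dataset An [sn_dataset()] with complete input/enrichment pairs.
#' @param top_fraction Fraction of genes (by enrichment count) used for the
#'   enrichment factors.
#' @param summary `"mean"` or `"median"` of the per-gene fold changes.
#' @return `sn_normalized` (values = log2(counts + 1) - log2(size factor)).
#' @export
radar_baseline <- function(dataset, top_fraction = 0.01,
                           summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(inherits(dataset, "sn_dataset"))
  samples <- dataset$samples
  in_ids <- samples$sample_id[samples$assay == "input"]
  en_ids <- samples$sample_id[samples$assay == "enrichment"]
  pair_of <- function(id) {
    pid <- samples$pair_id[samples$sample_id == id]
    mate <- samples$sample_id[samples$pair_id == pid &
                                samples$assay == "input"]
    if (length(mate) != 1) stop("unpaired enrichment sample: ", id)
    mate
  }
  in_counts <- dataset$counts[, in_ids, drop = FALSE]
  scal_in <- compute_scale_factors(in_counts, "DESeq")
  sf <- stats::setNames(numeric(ncol(dataset$counts)),
                        colnames(dataset$counts))
  sf[in_ids] <- scal_in$size_factors[in_ids]
  in_norm <- sweep(in_counts, 2, scal_in$size_factors[in_ids], "/")
  n_top <- max(1L, ceiling(top_fraction * nrow(dataset$counts)))
  for (e in en_ids) {
    mate <- pair_of(e)
    en <- dataset$counts[, e]
    top <- order(en, decreasing = TRUE)[seq_len(n_top)]
    denom <- in_norm[top, mate]
    ok <- denom > 0
    if (!all(ok))
      warning(sum(!ok), " zero-input gene(s) excluded from the top set for ", e)
    if (!any(ok)) stop("no usable top genes for ", e)
    f <- en[top][ok] / denom[ok]
    sf[e] <- if (summary == "mean") mean(f) else stats::median(f)
  }
  sf <- sf / exp(mean(log(sf)))
  values <- sweep(log_transform(dataset$counts), 2, log2(sf), "-")
  structure(list(values = values,
                 procedure = list(scaling = "RADAR", ruv_variant = "none",
                                  k = 0L),
                 scaling = structure(list(method = "RADAR", size_factors = sf,
                                          offsets = log2(sf),
                                          excluded_genes = character(0)),
                                     class = "sn_scaling"),
                 ruv = NULL),
            class = "sn_normalized")
}

#' Standalone RUVg baseline (no scaling step)
#'
#' The regression-only comparator: RUVg on the anchor set with `k` factors
#' and no size-factor scaling. With `k = 0` this is the identity (plain
#' log2(x+1)).
#'
#' @param dataset An [sn_dataset()].
#' @param gene_sets [select_gene_sets()] result (anchor set used).
#' @param k Number of unwanted-variation factors.
#' @return `sn_normalized`.
#' @export
ruvg_baseline <- function(dataset, gene_sets, k = 4) {
  if (k == 0)
    return(apply_procedure(dataset,
                           list(scaling = "none", ruv_variant = "none", k = 0L),
                           gene_sets))
  apply_procedure(dataset,
                  list(scaling = "none", ruv_variant = "RUVg", k = k),
                  gene_sets)
}
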