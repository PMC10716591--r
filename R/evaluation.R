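# Normalization performance evaluation: eight metrics per candidate
# (four average silhouette widths, two weighted coefficients of
# determination against evaluation factors, two relative-log-expression
# summaries) and rank aggregation into a single performance score.

METRIC_SIGNS <- c(BIO_SIM = 1, BATCH_SIM = -1, EN_SIM = 1, PAM_SIM = 1,
                  UV_COR = -1, WV_COR = 1, RLE_MED = -1, RLE_IQR = -1)

#' Sample scores on the leading expression principal components
#'
#' PCs of the gene-centered matrix (samples as observations), computed by
#' SVD via [stats::prcomp()].
#'
#' @param values Genes x samples matrix (log2 scale), or an `sn_normalized`.
#' @param n_pcs Number of components to return (capped at what exists).
#' @return Samples x n_pcs score matrix.
#' @export
expr_pcs <- function(values, n_pcs = 3) {
  if (inherits(values, "sn_normalized")) values <- values$values
  pr <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
}

#' Silhouette widths of a labeled configuration
#'
#' `sil(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' to the other members of i's cluster and `b(i)` the smallest mean distance
#' to another cluster; members of singleton clusters get 0 (declared
#' convention).
#'
#' @param embedding Samples x d numeric matrix.
#' @param labels Cluster labels (>= 2 non-empty clusters).
#' @return Numeric vector of per-sample widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(embedding))
  n <- nrow(D)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { sil[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    m <- max(a, b)
    sil[i] <- if (m == 0) 0 else (b - a) / m
  }
  sil
}

#' Silhouette-based similarity metrics of a normalization
#'
#' Average silhouette widths on the leading expression PCs, grouping samples
#' by the biological covariate (BIO_SIM), by batch (BATCH_SIM), and by assay
#' (EN_SIM); PAM_SIM is the maximum average silhouette over
#' partitioning-around-medoids clusterings for 2 to `max_pam_k` clusters.
#' Groupings with fewer than two levels yield `NA` (metric absent).
#'
#' @param normalized `sn_normalized` or genes x samples matrix.
#' @param samples Sample metadata with `group`, `batch`, `assay`.
#' @param n_pcs Number of expression PCs for the distance space.
#' @param bio_var Column of `samples` used for BIO_SIM.
#' @param max_pam_k Largest PAM cluster count tried (capped at samples - 1).
#' @return Named numeric vector: BIO_SIM, BATCH_SIM, EN_SIM, PAM_SIM.
#' @export
similarity_metrics <- function(normalized, samples, n_pcs = 3,
                               bio_var = "group", max_pam_k = 10) {
  pcs <- expr_pcs(normalized, n_pcs)
  avg_sil <- function(lab) {
    lab <- droplevels(as.factor(lab))
    if (nlevels(lab) < 2) return(NA_real_)
    mean(silhouette_widths(pcs, lab))
  }
  ks <- 2:min(max_pam_k, nrow(pcs) - 1)
  pam_sil <- max(vapply(ks, function(k) {
    cl <- cluster::pam(pcs, k, cluster.only = TRUE)
    if (length(unique(cl)) < 2) return(-1)
    mean(silhouette_widths(pcs, cl))
  }, numeric(1)))
  c(BIO_SIM = avg_sil(samples[[bio_var]]),
    BATCH_SIM = avg_sil(samples$batch),
    EN_SIM = avg_sil(samples$assay),
    PAM_SIM = pam_sil)
}

#' Weighted coefficient of determination
#'
#' Regresses each expression PC on all evaluation factors and pools the fits
#' by total sum of squares: `Rbar^2 = sum_k SSR_k / sum_k SST_k`.
#' Zero-variance PCs are excluded from both sums with a warning.
#'
#' @param pcs Samples x K matrix of expression PC scores.
#' @param eval_factors Samples x L matrix of evaluation factors.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_r2 <- function(pcs, eval_factors) {
  pcs <- as.matrix(pcs)
  eval_factors <- as.matrix(eval_factors)
  X <- cbind(1, eval_factors)
  sst <- sse <- 0
  for (j in seq_len(ncol(pcs))) {
    y <- pcs[, j]
    ss <- sum((y - mean(y))^2)
    if (ss < 1e-12) {
      warning("zero-variance expression PC ", j, " excluded")
      next
    }
    fit <- stats::lm.fit(X, y)
    sst <- sst + ss
    sse <- sse + sum(fit$residuals^2)
  }
  if (sst == 0) stop("no expression PC with positive variance")
  min(max(1 - sse / sst, 0), 1)
}

eval_factors_from <- function(raw_log, genes, n_factors) {
  Z <- raw_log[genes, , drop = FALSE]
  sds <- apply(Z, 1, stats::sd)
  Z <- Z[sds > 0, , drop = FALSE]
  if (nrow(Z) == 0) stop("no variable evaluation genes")
  Z <- (Z - rowMeans(Z)) / apply(Z, 1, stats::sd)
  sv <- svd(Z)
  kk <- min(n_factors, sum(sv$d > sv$d[1] * 1e-10))
  if (kk < n_factors)
    warning("evaluation set supports only ", kk, " factors")
  sv$v[, seq_len(kk), drop = FALSE]
}

#' Association of a normalization with unwanted and wanted variation
#'
#' Evaluation factors are the leading right-singular vectors of the
#' row-centered and scaled submatrix of *unnormalized* log counts for the
#' negative (UV) or positive (WV) evaluation genes; each candidate's
#' expression PCs are regressed on them and summarized by the weighted
#' coefficient of determination. Low UV_COR and high WV_COR are desirable.
#'
#' @param normalized `sn_normalized` or genes x samples matrix.
#' @param raw_log Genes x samples log2 matrix of the unnormalized counts.
#' @param gene_sets [select_gene_sets()] result.
#' @param n_pcs Expression PCs used.
#' @param n_factors Evaluation factors used (reduced with a warning when the
#'   evaluation set is smaller).
#' @return Named vector `c(UV_COR=, WV_COR=)`; `NA` where the evaluation set
#'   is empty.
#' @export
uv_wv_cor <- function(normalized, raw_log, gene_sets, n_pcs = 3,
                      n_factors = 3) {
  pcs <- expr_pcs(normalized, n_pcs)
  one <- function(genes) {
    if (length(genes) == 0) return(NA_real_)
    weighted_r2(pcs, eval_factors_from(raw_log, genes, n_factors))
  }
  c(UV_COR = one(gene_sets$negative_eval),
    WV_COR = one(gene_sets$positive_eval))
}

#' Relative log expression summaries
#'
#' RLE is each gene's deviation from its across-sample median on the log
#' scale. RLE_MED is the mean of squared per-sample median RLE; RLE_IQR is
#' the variance of the per-sample RLE interquartile ranges. Both are 0 for
#' perfectly comparable samples.
#'
#' @param normalized `sn_normalized` or genes x samples matrix (log2 scale).
#' @return Named vector `c(RLE_MED=, RLE_IQR=)`.
#' @export
rle_metrics <- function(normalized) {
  values <- if (inherits(normalized, "sn_normalized")) normalized$values
            else as.matrix(normalized)
  if (ncol(values) < 2) stop("RLE needs at least 2 samples")
  rle <- values - apply(values, 1, stats::median)
  med <- apply(rle, 2, stats::median)
  iqr <- apply(rle, 2, stats::IQR)
  c(RLE_MED = mean(med^2), RLE_IQR = stats::var(iqr))
}

#' All eight performance metrics for one normalization
#'
#' @param normalized `sn_normalized` object.
#' @param dataset The [sn_dataset()] the normalization came from (supplies
#'   sample metadata and the unnormalized counts for evaluation factors).
#' @param gene_sets [select_gene_sets()] result.
#' @param n_pcs,n_factors PC / factor counts (defaults 3).
#' @param bio_var Metadata column for BIO_SIM.
#' @return Named numeric vector of the eight metrics.
#' @export
metric_vector <- function(normalized, dataset, gene_sets, n_pcs = 3,
                          n_factors = 3, bio_var = "group") {
  raw_log <- log_transform(dataset$counts)
  c(similarity_metrics(normalized, dataset$samples, n_pcs, bio_var),
    uv_wv_cor(normalized, raw_log, gene_sets, n_pcs, n_factors),
    rle_metrics(normalized))
}

#' Rank-aggregate procedures into performance scores
#'
#' Each metric is multiplied by its orientation sign (+1 for BIO_SIM,
#' EN_SIM, PAM_SIM, WV_COR; -1 for BATCH_SIM, UV_COR, RLE_MED, RLE_IQR), so
#' large oriented values are good; procedures are ranked ascending per
#' metric (best gets the highest rank, ties averaged) and the performance
#' score is the mean rank. Metrics missing for any procedure are dropped for
#' all, with a warning.
#'
#' @param metric_table data.frame with one row per procedure: any identifier
#'   columns plus the metric columns named as in [metric_vector()].
#' @return The table with per-metric `rank_*` columns and
#'   `performance_score`, sorted by descending score.
#' @export
score_procedures <- function(metric_table) {
  stopifnot(is.data.frame(metric_table), nrow(metric_table) >= 2)
  present <- intersect(names(METRIC_SIGNS), names(metric_table))
  if (length(present) == 0) stop("no recognized metric columns")
  usable <- present[vapply(present, function(m)
    !anyNA(metric_table[[m]]), logical(1))]
  if (length(usable) < length(present))
    warning("metrics dropped (missing for some procedure): ",
            paste(setdiff(present, usable), collapse = ", "))
  if (length(usable) == 0) stop("no complete metric columns")
  ranks <- vapply(usable, function(m)
    rank(METRIC_SIGNS[m] * metric_table[[m]], ties.method = "average"),
    numeric(nrow(metric_table)))
  out <- metric_table
  colnames(ranks) <- paste0("rank_", usable)
  out <- cbind(out, ranks)
  out$performance_score <- rowMeans(ranks)
  out[order(-out$performance_score), , drop = FALSE]
}

#' Run and score a set of normalization procedures
#'
#' Applies every procedure, computes the eight metrics, and rank-aggregates
#' them. The top-scored normalization is re-applied and returned for direct
#' downstream use.
#'
#' @param dataset A filtered [sn_dataset()].
#' @param gene_sets [select_gene_sets()] result.
#' @param procedures data.frame from [enumerate_procedures()] (default: the
#'   full 96-procedure space).
#' @param n_pcs,n_factors,bio_var Passed to [metric_vector()].
#' @param keep_normalized Keep every normalized matrix (memory permitting)?
#' @return List of class `sn_evaluation`: `scores` (scored table), `metrics`
#'   (raw metric table), `best` (`sn_normalized` of the top procedure), and
#'   optionally `normalized` (named list).
#' @export
evaluate_procedures <- function(dataset, gene_sets,
                                procedures = enumerate_procedures(),
                                n_pcs = 3, n_factors = 3, bio_var = "group",
                                keep_normalized = FALSE) {
  norm_list <- if (keep_normalized) vector("list", nrow(procedures)) else NULL
  mets <- matrix(NA_real_, nrow(procedures), length(METRIC_SIGNS),
                 dimnames = list(NULL, names(METRIC_SIGNS)))
  for (i in seq_len(nrow(procedures))) {
    nm <- apply_procedure(dataset, procedures[i, ], gene_sets)
    mets[i, ] <- metric_vector(nm, dataset, gene_sets, n_pcs, n_factors,
                               bio_var)[names(METRIC_SIGNS)]
    if (keep_normalized) norm_list[[i]] <- nm
  }
  tab <- cbind(procedures, as.data.frame(mets))
  scores <- score_procedures(tab)
  best_row <- scores[1, c("scaling", "ruv_variant", "k")]
  best <- apply_procedure(dataset, best_row, gene_sets)
  out <- list(scores = scores, metrics = tab, best = best)
  if (keep_normalized) {
    names(norm_list) <- procedures$name
    out$normalized <- norm_list
  }
  structure(out, class = "sn_evaluation")
}
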