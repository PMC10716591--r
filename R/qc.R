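# Quality control: sample outlier detection on PC1, expression-based gene
# filtering, and sequencing-saturation assessment.

#' Generalized extreme studentized deviate (Rosner) outlier test
#'
#' Sequentially removes the most extreme value and compares each studentized
#' deviate to its critical value; the number of outliers is the largest step
#' whose statistic exceeds the critical value.
#'
#' @param x Numeric vector (length >= 4).
#' @param alpha Significance level.
#' @param max_outliers Maximum number of outliers to test for.
#' @return data.frame with one row per tested step: `index` (position in
#'   `x`), `r_stat`, `critical`, `flagged`.
#' @export
gesd_test <- function(x, alpha = 0.05, max_outliers = 1) {
  n <- length(x)
  if (n < 4) stop("Rosner's test needs at least 4 observations")
  if (n < max_outliers + 2)
    stop("need more observations than max_outliers + 2")
  idx <- seq_len(n)
  r_stat <- critical <- numeric(max_outliers)
  removed <- integer(max_outliers)
  xs <- x
  for (i in seq_len(max_outliers)) {
    dev <- abs(xs - mean(xs))
    j <- which.max(dev)
    r_stat[i] <- dev[j] / stats::sd(xs)
    removed[i] <- idx[j]
    p <- 1 - alpha / (2 * (n - i + 1))
    tq <- stats::qt(p, df = n - i - 1)
    critical[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    xs <- xs[-j]; idx <- idx[-j]
  }
  n_out <- if (any(r_stat > critical)) max(which(r_stat > critical)) else 0L
  data.frame(index = removed, r_stat = r_stat, critical = critical,
             flagged = seq_len(max_outliers) <= n_out)
}

#' Flag outlier samples on the first principal component
#'
#' Computes log2 counts-per-million (+1) as an approximate
#' variance-stabilizing transform, takes the top-variance genes, and applies
#' Rosner's generalized ESD test to PC1 scores.
#'
#' @param dataset An [sn_dataset()] with at least 4 samples.
#' @param n_top_genes Number of top-variance genes for the PCA.
#' @param alpha Significance level of the outlier test.
#' @param max_outliers Maximum outliers tested; defaults to 10% of samples
#'   (rounded up).
#' @return List with `outlier_samples` (sample ids flagged), `test` (the full
#'   [gesd_test()] table with sample ids), and `pc1` (scores).
#' @export
detect_outlier_samples <- function(dataset, n_top_genes = 20000,
                                   alpha = 0.05, max_outliers = NULL) {
  stopifnot(inherits(dataset, "sn_dataset"))
  n <- ncol(dataset$counts)
  if (n < 4) stop("outlier detection needs at least 4 samples")
  if (is.null(max_outliers)) max_outliers <- max(1L, ceiling(0.1 * n))
  if (n < max_outliers + 2)
    stop("fewer samples than max_outliers + 2")
  lib <- colSums(dataset$counts)
  if (any(lib <= 0)) stop("sample with zero total count")
  lcpm <- log2(sweep(dataset$counts, 2, lib, "/") * 1e6 + 1)
  v <- apply(lcpm, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(lcpm)))]
  pc <- stats::prcomp(t(lcpm[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  pc1 <- pc$x[, 1]
  tst <- gesd_test(pc1, alpha = alpha, max_outliers = max_outliers)
  tst$sample_id <- colnames(dataset$counts)[tst$index]
  list(outlier_samples = tst$sample_id[tst$flagged], test = tst,
       pc1 = stats::setNames(pc1, colnames(dataset$counts)))
}

#' Filter lowly expressed genes and excluded biotypes
#'
#' Keeps genes whose counts-per-million reach the CPM equivalent of
#' `min_count` at the median library size in at least as many samples as the
#' smallest experimental group (groups = assay crossed with biological
#' group), with the usual large-group damping (`10 + (n - 10) * min_prop`
#' when the smallest group exceeds 10 samples) and a minimum total count.
#' The rule is iterated on the surviving submatrix until the kept set is
#' self-consistent (every kept gene passes the threshold computed from the
#' kept data), which makes the filter exactly idempotent. Ribosomal-RNA and
#' TEC biotypes are then removed.
#'
#' @param dataset An [sn_dataset()].
#' @param min_count Count threshold defining the CPM cutoff.
#' @param min_prop Damping proportion for large groups.
#' @param min_total_count Minimum summed count across samples.
#' @return List with `dataset` (filtered), `kept_genes`,
#'   `n_removed_low_expression`, `n_removed_biotype`.
#' @export
filter_genes <- function(dataset, min_count = 20, min_prop = 0.7,
                         min_total_count = 15) {
  stopifnot(inherits(dataset, "sn_dataset"))
  counts <- dataset$counts
  grp <- interaction(dataset$samples$assay, dataset$samples$group, drop = TRUE)
  n_small <- min(table(grp))
  if (n_small > 10) n_small <- 10 + (n_small - 10) * min_prop
  keep_expr <- rep(TRUE, nrow(counts))
  for (it in 1:20) {
    sub <- counts[keep_expr, , drop = FALSE]
    if (nrow(sub) == 0) break
    lib <- colSums(sub)
    if (any(lib <= 0)) stop("sample with zero total count after filtering")
    cutoff <- min_count / stats::median(lib) * 1e6
    cpm <- sweep(counts, 2, lib, "/") * 1e6
    new_keep <- rowSums(cpm >= cutoff) >= n_small &
      rowSums(counts) >= min_total_count
    if (identical(new_keep, keep_expr)) break
    keep_expr <- new_keep
  }
  bad_biotype <- grepl("rRNA", dataset$genes$biotype, ignore.case = TRUE) |
    dataset$genes$biotype == "TEC"
  keep <- keep_expr & !bad_biotype
  if (!any(keep))
    stop("all genes removed by filtering; review min_count / biotype rules")
  list(dataset = dataset[keep, ],
       kept_genes = rownames(counts)[keep],
       n_removed_low_expression = sum(!keep_expr),
       n_removed_biotype = sum(keep_expr & bad_biotype))
}

#' Sequencing saturation by binomial downsampling
#'
#' For each subsampling fraction, reads are binomially thinned per gene and
#' sample and the mean number of endogenous genes detected above a count
#' threshold is recorded.
#'
#' @param dataset An [sn_dataset()].
#' @param fractions Subsampling fractions in `(0, 1]`.
#' @param detect_threshold A gene counts as detected when its reads exceed
#'   this value.
#' @param seed Integer seed for the thinning draws.
#' @return data.frame with columns `fraction` and `genes_detected` (mean over
#'   samples).
#' @export
saturation_curve <- function(dataset, fractions = seq(0.1, 1, by = 0.1),
                             detect_threshold = 10, seed = 1L) {
  stopifnot(inherits(dataset, "sn_dataset"))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  counts <- dataset$counts[dataset$genes$origin == "endogenous", ,
                           drop = FALSE]
  res <- vapply(fractions, function(f) {
    sub <- if (f == 1) counts
           else matrix(stats::rbinom(length(counts), size = as.integer(counts),
                                     prob = f),
                       nrow(counts), ncol(counts))
    mean(colSums(sub > detect_threshold))
  }, numeric(1))
  data.frame(fraction = fractions, genes_detected = res)
}
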