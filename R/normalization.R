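# Two-part normalization space: global scaling (TC, UQ, TMM, median-of-ratios,
# PoissonSeq) crossed with factor-regression adjustment (RUVg, RUVs, RUVse).
# The adjusted expression is Y* = Y - W alpha - O on the log2(x+1) scale,
# where O = log2(size factors) and W holds the unwanted-variation factors
# estimated by SVD of the (within-group-)centered anchor-gene submatrix.

SCALING_METHODS <- c("none", "TC", "UQ", "TMM", "DESeq", "PoissonSeq")
RUV_VARIANTS <- c("RUVg", "RUVs", "RUVse")

#' Per-sample size factors for a global scaling method
#'
#' Size factors are rescaled to geometric mean 1 so that procedures are
#' comparable; offsets are their log2.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @param method One of `"none"`, `"TC"` (total count), `"UQ"`
#'   (upper quartile of nonzero counts), `"TMM"` (trimmed mean of M-values
#'   against the sample whose upper quartile is closest to the mean upper
#'   quartile), `"DESeq"` (median ratio to the geometric-mean
#'   pseudo-reference, genes with any zero discarded), `"PoissonSeq"`
#'   (iterated depth estimate over Poisson-consistent genes; genes with
#'   total count below 5 discarded).
#' @param uq_prob Quantile used by UQ (and TMM reference selection).
#' @return List of class `sn_scaling`: `method`, `size_factors` (geometric
#'   mean 1), `offsets` (log2 size factors), `excluded_genes`.
#' @export
compute_scale_factors <- function(counts, method = SCALING_METHODS,
                                  uq_prob = 0.75) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (n < 2) stop("scaling needs at least 2 samples")
  excluded <- character(0)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample with zero total count")

  sf <- switch(method,
    none = rep(1, n),
    TC = lib,
    UQ = apply(counts, 2, function(y) {
      stats::quantile(y[y > 0], probs = uq_prob, names = FALSE, type = 7)
    }),
    TMM = {
      f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile,
                   probs = uq_prob, names = FALSE)
      ref <- which.min(abs(f75 - mean(f75)))
      f <- vapply(seq_len(n), function(j) {
        tmm_factor(counts[, j], counts[, ref], lib[j], lib[ref])
      }, numeric(1))
      lib * f
    },
    DESeq = {
      pos <- rowSums(counts > 0) == n
      if (!any(pos))
        stop("DESeq scaling impossible: no gene with nonzero counts in all ",
             "samples; consider another scaler")
      excluded <- rownames(counts)[!pos]
      ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
      apply(counts[pos, , drop = FALSE], 2, function(y)
        stats::median(y / ref))
    },
    PoissonSeq = {
      keep <- rowSums(counts) >= 5
      excluded <- rownames(counts)[!keep]
      sub <- counts[keep, , drop = FALSE]
      if (nrow(sub) < 2) stop("too few genes with total count >= 5")
      poissonseq_depth(sub)
    })
  sf <- sf / exp(mean(log(sf)))
  structure(list(method = method, size_factors = stats::setNames(sf, colnames(counts)),
                 offsets = stats::setNames(log2(sf), colnames(counts)),
                 excluded_genes = excluded),
            class = "sn_scaling")
}

# Trimmed mean of M-values between sample y and reference r (library sizes
# ny, nr): double trim (30% on M, 5% on A), precision weights from the
# delta-method binomial variances.
tmm_factor <- function(y, r, ny, nr, trim_m = 0.30, trim_a = 0.05) {
  ok <- y > 0 & r > 0
  y <- y[ok]; r <- r[ok]
  if (length(y) == 0) return(1)
  py <- y / ny; pr <- r / nr
  M <- log2(py / pr)
  A <- 0.5 * log2(py * pr)
  if (max(abs(M)) < 1e-6) return(1)
  v <- (ny - y) / (ny * y) + (nr - r) / (nr * r)
  keep_m <- M > stats::quantile(M, trim_m, names = FALSE) - 1e-12 &
            M < stats::quantile(M, 1 - trim_m, names = FALSE) + 1e-12
  keep_a <- A > stats::quantile(A, trim_a, names = FALSE) - 1e-12 &
            A < stats::quantile(A, 1 - trim_a, names = FALSE) + 1e-12
  keep <- keep_m & keep_a
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

# Iterative PoissonSeq-style depth estimate: start from total-count depths,
# recompute from genes whose Poisson goodness-of-fit statistic falls in the
# central 50%, until depths change by < tol.
poissonseq_depth <- function(counts, tol = 1e-6, max_iter = 20) {
  d <- colSums(counts) / sum(counts)
  total <- rowSums(counts)
  for (it in seq_len(max_iter)) {
    e <- outer(total, d)
    gof <- rowSums((counts - e)^2 / pmax(e, 1e-12))
    qs <- stats::quantile(gof, c(0.25, 0.75), names = FALSE)
    sel <- gof >= qs[1] & gof <= qs[2]
    if (!any(sel)) break
    d_new <- colSums(counts[sel, , drop = FALSE]) / sum(counts[sel, ])
    if (max(abs(d_new - d)) < tol) { d <- d_new; break }
    d <- d_new
  }
  d
}

#' Estimate factors of unwanted variation from control genes
#'
#' The control-gene submatrix of log expression is centered (globally for
#' RUVg, within replicate groups for RUVs/RUVse) and its SVD taken; the
#' sample-side singular vectors are the unwanted-variation factors W, and the
#' nuisance loadings alpha come from regressing every gene's log expression
#' on W (with an intercept, so gene means are preserved by the adjustment).
#'
#' For RUVs, replicate groups are sets of samples sharing all wanted
#' covariates as supplied by the caller; for RUVse the groups must be formed
#' within each assay level (crossed with the biological grouping), so
#' enrichment differences never enter the difference space.
#'
#' @param log_expr Genes x samples matrix on the log2 scale.
#' @param control_genes Gene ids (rownames of `log_expr`) used as negative
#'   controls.
#' @param variant `"RUVg"`, `"RUVs"`, or `"RUVse"`.
#' @param k Number of factors (>= 1).
#' @param replicate_groups Factor over samples defining replicate groups
#'   (required for RUVs/RUVse; every group needs >= 2 samples).
#' @return List of class `sn_ruv`: `variant`, `k`, `W` (samples x k),
#'   `alpha` (k x genes), `control_genes`.
#' @export
estimate_ruv_factors <- function(log_expr, control_genes,
                                 variant = RUV_VARIANTS, k,
                                 replicate_groups = NULL) {
  variant <- match.arg(variant)
  if (k < 1) stop("k must be at least 1")
  log_expr <- as.matrix(log_expr)
  if (!all(control_genes %in% rownames(log_expr)))
    stop("control genes absent from the expression matrix")
  Zc <- log_expr[control_genes, , drop = FALSE]
  n <- ncol(Zc)
  if (k > n) stop("k cannot exceed the number of samples")

  if (variant == "RUVg") {
    Zcent <- Zc - rowMeans(Zc)
  } else {
    if (is.null(replicate_groups))
      stop(variant, " requires replicate_groups")
    grp <- as.factor(replicate_groups)
    if (length(grp) != n) stop("replicate_groups length mismatch")
    sizes <- table(grp)
    if (any(sizes < 2))
      stop("singleton replicate group(s) for ", variant, ": ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    Zcent <- Zc
    for (g in levels(grp)) {
      j <- which(grp == g)
      Zcent[, j] <- Zc[, j, drop = FALSE] - rowMeans(Zc[, j, drop = FALSE])
    }
  }
  sv <- svd(Zcent)
  admissible <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  if (k > admissible)
    stop("k = ", k, " exceeds the admissible rank (", admissible,
         ") of the centered control matrix")
  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(log_expr)
  colnames(W) <- paste0("W", seq_len(k))

  A <- cbind(1, W)
  coefs <- solve(crossprod(A), crossprod(A, t(log_expr)))
  alpha <- coefs[-1, , drop = FALSE]
  structure(list(variant = variant, k = k, W = W, alpha = alpha,
                 control_genes = control_genes),
            class = "sn_ruv")
}

#' Adjusted expression from offsets and unwanted-variation factors
#'
#' Computes `Y* = Y - W alpha - O` on the log2 scale: per-sample offsets are
#' subtracted first, then the fitted unwanted-variation component. With no
#' RUV fit and no scaling this is the identity.
#'
#' @param log_expr Genes x samples matrix on the log2 scale.
#' @param ruv Optional [estimate_ruv_factors()] fit.
#' @param scaling Optional [compute_scale_factors()] result, or a per-sample
#'   numeric vector of log2 offsets.
#' @param procedure Optional procedure descriptor stored as provenance.
#' @return Object of class `sn_normalized` with elements `values` (genes x
#'   samples, log2 scale), `procedure`, `scaling`, `ruv`.
#' @export
adjust_counts <- function(log_expr, ruv = NULL, scaling = NULL,
                          procedure = NULL) {
  values <- as.matrix(log_expr)
  if (!is.null(scaling)) {
    off <- if (inherits(scaling, "sn_scaling")) scaling$offsets else scaling
    if (length(off) != ncol(values)) stop("offset length mismatch")
    values <- sweep(values, 2, off, "-")
  }
  if (!is.null(ruv)) {
    stopifnot(inherits(ruv, "sn_ruv"))
    if (nrow(ruv$W) != ncol(values) || ncol(ruv$alpha) != nrow(values))
      stop("RUV fit dimensions do not match the expression matrix")
    values <- values - t(ruv$W %*% ruv$alpha)
  }
  if (!all(is.finite(values))) stop("non-finite values after adjustment")
  structure(list(values = values, procedure = procedure,
                 scaling = scaling, ruv = ruv),
            class = "sn_normalized")
}

#' Enumerate the combinatorial normalization space
#'
#' Cross product of the raw baseline plus the given scaling methods with
#' no-RUV plus every RUV variant at `k = 1..k_max`, deduplicated, in
#' deterministic order. The unnormalized baseline (`"none"`) is always part
#' of the scaling axis, so the default space (five scalers, three variants,
#' `k_max = 5`) has 6 x 16 = 96 procedures.
#'
#' @param scaling_set Character vector of scaling methods (see
#'   [compute_scale_factors()]); the `"none"` baseline is added implicitly.
#' @param ruv_variants Character vector of RUV variants.
#' @param k_max Largest number of unwanted-variation factors.
#' @return data.frame with columns `scaling`, `ruv_variant` (`"none"` for the
#'   no-RUV rows), `k` (0 when no RUV), and a unique `name`.
#' @export
enumerate_procedures <- function(scaling_set = setdiff(SCALING_METHODS, "none"),
                                 ruv_variants = RUV_VARIANTS, k_max = 5) {
  if (length(scaling_set) == 0) stop("empty scaling_set")
  if (k_max < 1) stop("k_max must be >= 1")
  scaling_set <- unique(c("none", scaling_set))
  bad <- setdiff(scaling_set, SCALING_METHODS)
  if (length(bad)) stop("unknown scaling method: ", paste(bad, collapse = ", "))
  bad <- setdiff(ruv_variants, RUV_VARIANTS)
  if (length(bad)) stop("unknown RUV variant: ", paste(bad, collapse = ", "))
  ruv_part <- rbind(data.frame(ruv_variant = "none", k = 0L),
                    expand.grid(ruv_variant = ruv_variants,
                                k = seq_len(k_max),
                                stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
  out <- merge(data.frame(scaling = unique(scaling_set)), unique(ruv_part),
               by = NULL)
  out <- out[order(match(out$scaling, SCALING_METHODS),
                   match(out$ruv_variant, c("none", RUV_VARIANTS)), out$k), ]
  rownames(out) <- NULL
  out$name <- ifelse(out$ruv_variant == "none",
                     out$scaling,
                     paste(out$scaling, out$ruv_variant, out$k, sep = "_"))
  out
}

ruv_groups <- function(samples, variant) {
  switch(variant,
    RUVs = as.factor(samples$group),
    RUVse = interaction(samples$assay, samples$group, drop = TRUE),
    stop("no replicate grouping for variant ", variant))
}

#' Apply one normalization procedure to a dataset
#'
#' Composes size-factor scaling, the log2(x+1) transform with offsets, and
#' (when requested) RUV adjustment anchored on the control gene set. RUVs
#' replicate groups pool the assay levels within each biological group; RUVse
#' groups are assay level crossed with biological group, protecting the
#' enrichment contrast.
#'
#' @param dataset An [sn_dataset()].
#' @param procedure One row of [enumerate_procedures()], or a list with
#'   `scaling`, `ruv_variant`, `k`.
#' @param gene_sets A [select_gene_sets()] result (or any list with an
#'   `anchor` element); required when `ruv_variant != "none"`.
#' @return An `sn_normalized` object (see [adjust_counts()]).
#' @export
apply_procedure <- function(dataset, procedure, gene_sets = NULL) {
  stopifnot(inherits(dataset, "sn_dataset"))
  proc <- as.list(procedure)[c("scaling", "ruv_variant", "k")]
  proc$scaling <- as.character(proc$scaling)
  proc$ruv_variant <- as.character(proc$ruv_variant)
  proc$k <- as.integer(proc$k)
  if ((proc$ruv_variant == "none") != (proc$k == 0))
    stop("ruv_variant 'none' requires k = 0 and vice versa")

  scal <- compute_scale_factors(dataset$counts, proc$scaling)
  log_expr <- log_transform(dataset$counts)
  scaled <- sweep(log_expr, 2, scal$offsets, "-")

  ruv <- NULL
  if (proc$ruv_variant != "none") {
    if (is.null(gene_sets) || length(gene_sets$anchor) == 0)
      stop("RUV adjustment requires a non-empty anchor gene set")
    groups <- if (proc$ruv_variant == "RUVg") NULL
              else ruv_groups(dataset$samples, proc$ruv_variant)
    ruv <- estimate_ruv_factors(scaled, gene_sets$anchor,
                                variant = proc$ruv_variant, k = proc$k,
                                replicate_groups = groups)
  }
  out <- adjust_counts(log_expr, ruv = ruv, scaling = scal, procedure = proc)
  out$gene_sets <- lapply(gene_sets[c("anchor", "negative_eval",
                                      "positive_eval")], length)
  out
}
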