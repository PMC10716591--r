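# Negative-binomial GLM likelihood-ratio testing: the shared inferential
# engine behind control-gene selection and enrichment calling. Self-contained
# IRLS fitter with method-of-moments dispersion estimation shrunk toward a
# mean-dispersion trend.

# Written with lgamma so it stays valid (and silent) for the non-integer
# working responses used by the prior-count-stabilized fold-change fit.
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 0) return(sum(y * log(mu) - mu - lgamma(y + 1)))
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        y * log(phi * mu / (1 + phi * mu)) - r * log1p(phi * mu))
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  yl <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi <= 0) 2 * sum(yl - (y - mu))
  else 2 * sum(yl - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
}

# IRLS fit of a negative-binomial GLM with log link and fixed dispersion.
# Convergence: relative deviance change < tol or max_iter iterations.
nb_irls <- function(y, X, offset = NULL, phi = 0, tol = 1e-8, max_iter = 100) {
  n <- length(y)
  if (is.null(offset)) offset <- numeric(n)
  p <- ncol(X)
  # initialize from a linear fit on shifted log counts
  z0 <- log(y + 0.5) - offset
  beta <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, p))
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    eta_new <- pmin(pmax(drop(X %*% beta_new) + offset, -30), 30)
    dev_new <- nb_deviance(y, exp(eta_new), phi)
    if (!is.finite(dev_new)) break
    beta <- beta_new
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu, deviance = dev,
       loglik = nb_loglik(y, mu, phi), converged = converged)
}

check_full_rank <- function(X, label = "design") {
  if (qr(X)$rank < ncol(X))
    stop(label, " matrix is rank deficient")
  invisible(TRUE)
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Method-of-moments estimate per gene from Poisson-fitted means under the
#' design, followed by shrinkage toward a lowess mean-dispersion trend; the
#' shrinkage weight is the residual degrees of freedom against a fixed prior
#' weight, so sparse designs borrow more from the trend.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param design Per-sample design matrix (full column rank, at least one
#'   residual degree of freedom).
#' @param offsets Optional per-sample offsets on the natural-log scale;
#'   defaults to centered log library sizes.
#' @param prior_df Prior weight (in residual-df units) given to the trend.
#' @return Strictly positive numeric vector of per-gene dispersions.
#' @export
estimate_dispersions <- function(counts, design, offsets = NULL,
                                 prior_df = 10) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  p <- ncol(design)
  check_full_rank(design)
  if (n - p < 1) stop("no residual degrees of freedom in the design")
  if (is.null(offsets)) {
    ls <- colSums(counts)
    if (any(ls <= 0)) stop("sample with zero total count")
    offsets <- log(ls) - mean(log(ls))
  }
  ngenes <- nrow(counts)
  phi_mom <- numeric(ngenes)
  abundance <- numeric(ngenes)
  corr <- n / (n - p)
  for (g in seq_len(ngenes)) {
    y <- counts[g, ]
    if (all(y == 0)) { phi_mom[g] <- 0; abundance[g] <- -Inf; next }
    fit <- nb_irls(y, design, offsets, phi = 0)
    mu <- fit$mu
    phi_mom[g] <- max(0, sum((y - mu)^2 * corr - mu) / sum(mu^2))
    abundance[g] <- mean(log2(y / exp(offsets) + 0.5))
  }
  ok <- is.finite(abundance)
  trend <- rep(max(mean(phi_mom[ok]), 1e-6), ngenes)
  if (sum(ok) >= 20) {
    lo <- stats::lowess(abundance[ok], phi_mom[ok], f = 0.5)
    trend[ok] <- pmax(stats::approx(lo$x, lo$y, xout = abundance[ok],
                                    rule = 2, ties = mean)$y, 1e-6)
  }
  df <- n - p
  phi <- (prior_df * trend + df * phi_mom) / (prior_df + df)
  pmax(phi, 1e-8)
}

#' Likelihood-ratio tests from nested negative-binomial GLMs
#'
#' Per gene, fits the negative-binomial GLM (log link) under the full and the
#' reduced design with a shared dispersion and reports the likelihood-ratio
#' statistic, a chi-square p value with degrees of freedom equal to the rank
#' difference, a coefficient-based log2 fold change for the dropped covariate
#' (stabilized by refitting on counts plus a small prior count), and
#' Benjamini-Hochberg adjusted FDR.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param design_full,design_reduced Per-sample design matrices; the reduced
#'   columns must span a strict subspace of the full columns.
#' @param offsets Optional per-sample natural-log offsets (default: centered
#'   log library sizes) or a genes x samples offset matrix.
#' @param dispersions Optional per-gene dispersions; estimated under the full
#'   design when missing.
#' @param prior_count Pseudo-count added when computing the reported log2
#'   fold change (not the test itself).
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `lr_stat`,
#'   `p_value`, `fdr`, `converged`. All-zero genes get `lr_stat = 0`,
#'   `p_value = 1` by convention.
#' @export
nb_glm_lrt <- function(counts, design_full, design_reduced, offsets = NULL,
                       dispersions = NULL, prior_count = 0.125) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  design_full <- as.matrix(design_full)
  design_reduced <- as.matrix(design_reduced)
  check_full_rank(design_full, "full design")
  check_full_rank(design_reduced, "reduced design")
  qf <- qr(design_full)
  Qf <- qr.Q(qf)
  resid_red <- design_reduced - Qf %*% (t(Qf) %*% design_reduced)
  if (max(abs(resid_red)) > 1e-8)
    stop("designs are not nested: reduced columns outside the full column space")
  df_test <- qf$rank - qr(design_reduced)$rank
  if (df_test < 1) stop("designs are not nested: no tested degrees of freedom")

  if (is.null(offsets)) {
    ls <- colSums(counts)
    if (any(ls <= 0)) stop("sample with zero total count")
    offsets <- log(ls) - mean(log(ls))
  }
  off_mat <- if (is.matrix(offsets)) offsets
             else matrix(offsets, nrow(counts), n, byrow = TRUE)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, design_full,
                                        offsets = if (is.matrix(offsets)) NULL
                                                  else offsets)

  # single tested coefficient: identify the full-design columns outside the
  # reduced span, so a log2 fold change can be reported for df = 1 tests
  Qr <- qr.Q(qr(design_reduced))
  out_cols <- which(apply(design_full, 2, function(v) {
    r <- v - Qr %*% (t(Qr) %*% v)
    sqrt(sum(r^2)) > 1e-8 * (sqrt(sum(v^2)) + 1)
  }))
  lfc_col <- if (df_test == 1 && length(out_cols) == 1) out_cols else NA_integer_

  ngenes <- nrow(counts)
  lr <- numeric(ngenes); pv <- numeric(ngenes); lfc <- numeric(ngenes)
  conv <- logical(ngenes)
  for (g in seq_len(ngenes)) {
    y <- counts[g, ]
    o <- off_mat[g, ]
    if (all(y == 0)) { lr[g] <- 0; pv[g] <- 1; lfc[g] <- 0; conv[g] <- TRUE; next }
    phi <- dispersions[g]
    f_full <- nb_irls(y, design_full, o, phi)
    f_red <- nb_irls(y, design_reduced, o, phi)
    lr[g] <- max(0, 2 * (f_full$loglik - f_red$loglik))
    pv[g] <- stats::pchisq(lr[g], df = df_test, lower.tail = FALSE)
    conv[g] <- f_full$converged && f_red$converged
    if (!is.na(lfc_col)) {
      f_pc <- nb_irls(y + prior_count, design_full, o, phi)
      lfc[g] <- f_pc$beta[lfc_col] / log(2)
    } else lfc[g] <- NA_real_
  }
  gene_id <- rownames(counts)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(ngenes))
  data.frame(gene_id = gene_id, log2_fold_change = lfc, lr_stat = lr,
             p_value = pv, fdr = bh_adjust(pv), converged = conv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p values in `[0, 1]` (no missing values).
#' @return Adjusted values in `[0, 1]`, monotone in the ordering of `p_values`.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values)) stop("missing values in p_values")
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
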