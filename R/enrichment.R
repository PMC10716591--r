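# Enrichment calling and per-sample modification levels from a selected
# normalization.

#' Call enriched (NAD-capped) transcripts
#'
#' Tests the enrichment-versus-input effect per gene with the
#' negative-binomial likelihood-ratio test. In the default
#' `"covariate_adjusted"` formulation the model is fit on the raw counts
#' with the procedure's size-factor offsets and its unwanted-variation
#' factors W as nuisance covariates, so the adjustment is used exactly once;
#' `"normalized_refit"` instead refits on pseudo-counts back-transformed
#' from the adjusted matrix. A gene is called when its fold change reaches
#' `fc_threshold` (boundary inclusive) and its BH-adjusted FDR is below
#' `fdr_threshold`.
#'
#' Endogenous genes and the two synthetic spike-ins are tested; the
#' synthetic transcripts act as sensitivity/specificity controls (the
#' partially NAD-capped one should be called, the fully m7G-capped one
#' should not) and are distinguished by the `origin` column.
#'
#' @param normalized `sn_normalized` from [apply_procedure()].
#' @param dataset The [sn_dataset()] the normalization came from.
#' @param fc_threshold Minimum fold change (natural scale, default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param mode `"covariate_adjusted"` or `"normalized_refit"`.
#' @return data.frame: `gene_id`, `origin`, `log2_fc`, `lr_stat`, `p_value`,
#'   `fdr`, `is_nad_rna`.
#' @export
find_enrichment <- function(normalized, dataset, fc_threshold = 2,
                            fdr_threshold = 0.05,
                            mode = c("covariate_adjusted",
                                     "normalized_refit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(normalized, "sn_normalized"),
            inherits(dataset, "sn_dataset"))
  samples <- dataset$samples
  if (length(unique(samples$assay)) < 2)
    stop("both assay levels are required")
  sel <- dataset$genes$origin %in% c("endogenous", "synthetic_nad",
                                     "synthetic_m7g")
  has_group <- length(unique(samples$group)) > 1
  base <- if (has_group) stats::model.matrix(~group, data = samples)
          else stats::model.matrix(~1, data = samples)
  # input is the reference level, so the coefficient is enrichment-vs-input
  assay_col <- matrix(as.numeric(samples$assay == "enrichment"), ncol = 1)

  if (mode == "covariate_adjusted") {
    counts <- dataset$counts[sel, , drop = FALSE]
    W <- if (!is.null(normalized$ruv)) normalized$ruv$W else NULL
    X_red <- cbind(base, W)
    X_full <- cbind(X_red, enrich = assay_col)
    offsets <- if (!is.null(normalized$scaling))
      log(2) * normalized$scaling$offsets else NULL
  } else {
    counts <- round(pmax(2^normalized$values[rownames(normalized$values) %in%
                                               rownames(dataset$counts)[sel], ,
                                             drop = FALSE] - 1, 0))
    X_red <- base
    X_full <- cbind(base, enrich = assay_col)
    offsets <- rep(0, ncol(counts))
  }
  res <- nb_glm_lrt(counts, X_full, X_red, offsets = offsets)
  res$origin <- dataset$genes$origin[match(res$gene_id, dataset$genes$gene_id)]
  res$log2_fc <- res$log2_fold_change
  res$is_nad_rna <- res$log2_fc >= log2(fc_threshold) &
    res$fdr < fdr_threshold
  res[, c("gene_id", "origin", "log2_fc", "lr_stat", "p_value", "fdr",
          "is_nad_rna")]
}

#' Per-pair modification levels
#'
#' Log2 fold change of adjusted expression between each enrichment library
#' and its paired input library — the per-sample modification level of each
#' gene.
#'
#' @param normalized `sn_normalized` (log2-scale values).
#' @param samples Sample metadata with `sample_id`, `assay`, `pair_id`.
#' @return Genes x pairs matrix (columns named by `pair_id`).
#' @export
modification_levels <- function(normalized, samples) {
  values <- if (inherits(normalized, "sn_normalized")) normalized$values
            else as.matrix(normalized)
  pairs <- unique(samples$pair_id)
  en_id <- in_id <- character(length(pairs))
  bad <- character(0)
  for (i in seq_along(pairs)) {
    sub <- samples[samples$pair_id == pairs[i], ]
    e <- sub$sample_id[sub$assay == "enrichment"]
    s <- sub$sample_id[sub$assay == "input"]
    if (length(e) != 1 || length(s) != 1) { bad <- c(bad, pairs[i]); next }
    en_id[i] <- e; in_id[i] <- s
  }
  if (length(bad))
    stop("incomplete input/enrichment pair(s): ", paste(bad, collapse = ", "))
  out <- values[, en_id, drop = FALSE] - values[, in_id, drop = FALSE]
  colnames(out) <- pairs
  out
}
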