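# Control-gene-set selection: the three gene lists that drive normalization
# (anchor set, from spike-ins) and evaluation (negative / positive evaluation
# sets, from endogenous genes), all ranked by negative-binomial likelihood
# ratio. Ties are broken by gene order, so rankings are deterministic.

lrt_on_subset <- function(dataset, origin, design_full, design_reduced) {
  sel <- dataset$genes$origin %in% origin
  if (!any(sel)) stop("no genes of origin ", paste(origin, collapse = "/"),
                      " in the dataset")
  counts <- dataset$counts[sel, , drop = FALSE]
  nb_glm_lrt(counts, design_full, design_reduced)
}

#' Select the anchor set of least-enriched spike-in genes
#'
#' Tests the enrichment (assay) effect on spike-in genes with the NB
#' likelihood-ratio test and returns the `n` genes least affected (ascending
#' likelihood ratio). Batch is deliberately left out of the model so batch
#' variation survives in the anchor genes — that is exactly what the RUV step
#' later consumes.
#'
#' @param dataset An [sn_dataset()] with spike-in genes and both assay levels.
#' @param n Requested anchor-set size.
#' @return Character vector of gene ids (with a warning if the spike-in pool
#'   is smaller than `n`). The full ranking is attached as attribute
#'   `"ranking"`.
#' @export
select_anchor_set <- function(dataset, n = 1000) {
  if (length(unique(dataset$samples$assay)) < 2)
    stop("both assay levels are required to rank enrichment")
  X_full <- stats::model.matrix(~assay, data = dataset$samples)
  X_red <- X_full[, 1, drop = FALSE]
  res <- lrt_on_subset(dataset, "spikein", X_full, X_red)
  ord <- order(res$lr_stat, seq_len(nrow(res)))
  if (n > nrow(res)) {
    warning("requested anchor size ", n, " exceeds the spike-in pool (",
            nrow(res), "); returning all spike-in genes")
    n <- nrow(res)
  }
  out <- res$gene_id[ord][seq_len(n)]
  attr(out, "ranking") <- res[ord, ]
  out
}

#' Select negative evaluation genes (least varied endogenous genes)
#'
#' Tests all covariates of interest (assay and biological group) jointly
#' against the intercept on endogenous genes and returns the `n` genes with
#' the smallest likelihood ratios — genes whose residual variation reflects
#' handling effects rather than wanted biology.
#'
#' @param dataset An [sn_dataset()].
#' @param n Requested set size.
#' @param exclude Gene ids barred from selection (used to keep the negative
#'   and positive evaluation sets disjoint).
#' @return Character vector of gene ids with attribute `"ranking"`.
#' @export
select_negative_eval <- function(dataset, n = 500, exclude = character(0)) {
  covars <- if (length(unique(dataset$samples$group)) > 1) ~assay + group
            else ~assay
  X_full <- stats::model.matrix(covars, data = dataset$samples)
  X_red <- X_full[, 1, drop = FALSE]
  res <- lrt_on_subset(dataset, "endogenous", X_full, X_red)
  res <- res[!(res$gene_id %in% exclude), , drop = FALSE]
  ord <- order(res$lr_stat, seq_len(nrow(res)))
  if (n > nrow(res)) {
    warning("requested size ", n, " exceeds the candidate pool (",
            nrow(res), ")")
    n <- nrow(res)
  }
  out <- res$gene_id[ord][seq_len(n)]
  attr(out, "ranking") <- res[ord, ]
  out
}

#' Select positive evaluation genes (most enriched endogenous genes)
#'
#' Tests the assay effect on endogenous genes and returns the `n` most
#' significantly enriched (descending likelihood ratio) — the genes whose
#' signal a good normalization must preserve.
#'
#' @param dataset An [sn_dataset()].
#' @param n Requested set size.
#' @return Character vector of gene ids with attribute `"ranking"`.
#' @export
select_positive_eval <- function(dataset, n = 500) {
  if (length(unique(dataset$samples$assay)) < 2)
    stop("both assay levels are required to rank enrichment")
  X_full <- stats::model.matrix(~assay, data = dataset$samples)
  X_red <- X_full[, 1, drop = FALSE]
  res <- lrt_on_subset(dataset, "endogenous", X_full, X_red)
  ord <- order(-res$lr_stat, seq_len(nrow(res)))
  if (n > nrow(res)) {
    warning("requested size ", n, " exceeds the candidate pool (",
            nrow(res), ")")
    n <- nrow(res)
  }
  out <- res$gene_id[ord][seq_len(n)]
  attr(out, "ranking") <- res[ord, ]
  out
}

#' Select all three control gene sets
#'
#' Convenience wrapper running [select_anchor_set()],
#' [select_positive_eval()] and [select_negative_eval()]; the negative set
#' excludes positive-set genes so the two evaluation sets are disjoint.
#'
#' @param dataset An [sn_dataset()].
#' @param n_anchor,n_negative,n_positive Requested sizes.
#' @return List of class `sn_gene_sets` with elements `anchor`,
#'   `negative_eval`, `positive_eval`, `sizes`.
#' @export
select_gene_sets <- function(dataset, n_anchor = 1000, n_negative = 500,
                             n_positive = 500) {
  anchor <- select_anchor_set(dataset, n_anchor)
  positive <- select_positive_eval(dataset, n_positive)
  negative <- select_negative_eval(dataset, n_negative, exclude = positive)
  structure(list(anchor = as.character(anchor),
                 negative_eval = as.character(negative),
                 positive_eval = as.character(positive),
                 sizes = c(n_anchor = length(anchor),
                           n_neg = length(negative),
                           n_pos = length(positive))),
            class = "sn_gene_sets")
}
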