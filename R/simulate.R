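#' Simulation parameters for a spike-in enrichment experiment
#'
#' Defines the generative model for [simulate_dataset()]: paired input and
#' enrichment libraries for subjects spread over biological groups and
#' processing batches, with endogenous genes, an exogenous spike-in pool added
#' in equal amounts to every sample, and two synthetic spike-in transcripts —
#' one partially NAD-capped (and therefore enriched by capture) and one fully
#' m7G-capped (not enriched).
#'
#' @param n_endogenous,n_spikein Number of endogenous and spike-in genes.
#' @param n_samples_per_group Subjects per biological group; every subject
#'   contributes one input and one enrichment library sharing a `pair_id`.
#' @param n_batches Number of processing batches; both libraries of a subject
#'   share its batch.
#' @param n_groups Number of biological groups.
#' @param batch_sd Log2-scale standard deviation of per-gene batch loadings
#'   (`batch_mode = "factor"`) or of the per-batch global shift
#'   (`batch_mode = "shift"`).
#' @param n_batch_factors Rank of the planted batch structure in factor mode.
#' @param enrichment_lfc Log2 fold change gained by true NAD-capped genes in
#'   enrichment libraries.
#' @param frac_nad Fraction of endogenous genes that are NAD-capped.
#' @param frac_group Fraction of endogenous genes carrying biological group
#'   effects.
#' @param group_sd Log2-scale SD of the planted group effects.
#' @param frac_spikein_enriched Fraction of spike-in genes that respond to the
#'   capture step (non-specific carry-through); the remainder are the clean
#'   anchor pool.
#' @param spike_enrichment_lfc Log2 fold change of the responding spike-ins.
#' @param synthetic_nad_lfc Log2 fold change of the partially NAD-capped
#'   synthetic spike-in under enrichment; the m7G synthetic spike-in gets 0.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson counts).
#' @param lib_size_range Min/max expected library size; per-library sizes are
#'   drawn uniformly in this range.
#' @param batch_mode `"factor"` plants low-rank batch structure (Gaussian
#'   loadings x batch factors), the generative family the factor-regression
#'   adjustment assumes; `"shift"` plants a uniform per-batch shift on a
#'   random half of the genes (indicator loadings) to probe robustness under
#'   misspecification.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `sn_sim_params`.
#' @export
sim_params <- function(n_endogenous = 2000, n_spikein = 1000,
                       n_samples_per_group = 3, n_batches = 3, n_groups = 2,
                       batch_sd = 1, n_batch_factors = 2,
                       enrichment_lfc = 2, frac_nad = 0.05,
                       frac_group = 0.1, group_sd = 0.5,
                       frac_spikein_enriched = 0.05,
                       spike_enrichment_lfc = enrichment_lfc,
                       synthetic_nad_lfc = 2,
                       dispersion = 0.1, lib_size_range = c(1e5, 2e5),
                       batch_mode = c("factor", "shift"), seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  p <- list(n_endogenous = n_endogenous, n_spikein = n_spikein,
            n_samples_per_group = n_samples_per_group, n_batches = n_batches,
            n_groups = n_groups, batch_sd = batch_sd,
            n_batch_factors = n_batch_factors,
            enrichment_lfc = enrichment_lfc, frac_nad = frac_nad,
            frac_group = frac_group, group_sd = group_sd,
            frac_spikein_enriched = frac_spikein_enriched,
            spike_enrichment_lfc = spike_enrichment_lfc,
            synthetic_nad_lfc = synthetic_nad_lfc,
            dispersion = dispersion, lib_size_range = lib_size_range,
            batch_mode = batch_mode, seed = as.integer(seed))
  stopifnot(n_endogenous >= 1, n_spikein >= 1, n_samples_per_group >= 1,
            n_batches >= 1, n_groups >= 1, dispersion >= 0,
            frac_nad >= 0, frac_nad <= 1, frac_group >= 0, frac_group <= 1,
            length(lib_size_range) == 2, all(lib_size_range > 0))
  if (n_batches < 2 && batch_sd > 0)
    stop("batch_sd > 0 requires at least 2 batches")
  if (batch_mode == "factor" && batch_sd > 0 &&
      n_batch_factors > max(1, n_batches - 1))
    stop("n_batch_factors must be <= n_batches - 1 for identifiable structure")
  class(p) <- "sn_sim_params"
  p
}

#' Simulate a paired input/enrichment spike-in dataset with known truth
#'
#' Draws negative-binomial counts whose log2 mean is
#' baseline + library offset + batch structure + assay enrichment effect
#' (true NAD genes, responding spike-ins, and the synthetic NAD spike-in
#' only) + group effects (endogenous genes only). Both libraries of a pair
#' share the subject's biological mean; columns are scaled so expected
#' library sizes hit the drawn targets.
#'
#' @param params An [sim_params()] object.
#' @return A list with elements `dataset` (an [sn_dataset()]) and `truth`
#'   (planted NAD gene ids, batch factors and loadings, group and enrichment
#'   effects, expected library sizes).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sn_sim_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)
  p <- params

  n_subj <- p$n_groups * p$n_samples_per_group
  subj <- data.frame(
    subj_id = sprintf("S%02d", seq_len(n_subj)),
    group = rep(paste0("G", seq_len(p$n_groups)), each = p$n_samples_per_group),
    batch = paste0("B", rep_len(seq_len(p$n_batches), n_subj)),
    stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = as.vector(t(outer(subj$subj_id, c("in", "en"), paste, sep = "_"))),
    batch = rep(subj$batch, each = 2),
    assay = rep(c("input", "enrichment"), times = n_subj),
    group = rep(subj$group, each = 2),
    pair_id = rep(subj$subj_id, each = 2),
    stringsAsFactors = FALSE)
  n_samp <- nrow(samples)

  n_genes <- p$n_endogenous + p$n_spikein + 2L
  gene_id <- c(sprintf("ENDO%05d", seq_len(p$n_endogenous)),
               sprintf("SPIKE%05d", seq_len(p$n_spikein)),
               "SYN_NAD", "SYN_M7G")
  origin <- c(rep("endogenous", p$n_endogenous),
              rep("spikein", p$n_spikein),
              "synthetic_nad", "synthetic_m7g")
  biotype <- rep("protein_coding", n_genes)
  genes <- data.frame(gene_id = gene_id, origin = origin, biotype = biotype,
                      stringsAsFactors = FALSE)

  # baseline log2 abundance (relative); the spread is kept moderate so that
  # no single transcript dominates a library and expected library sizes are
  # recoverable from column totals; synthetic spike-ins sit high, as in a
  # real spike-in mix
  base_l2 <- stats::rnorm(n_genes, mean = 5, sd = 1.5)
  base_l2[n_genes - 1L] <- 9
  base_l2[n_genes] <- 9

  # planted batch structure
  batch_idx <- match(samples$batch, paste0("B", seq_len(p$n_batches)))
  if (p$batch_sd > 0 && p$n_batches >= 2) {
    if (p$batch_mode == "factor") {
      b <- p$n_batch_factors
      fac_batch <- matrix(stats::rnorm(p$n_batches * b), p$n_batches, b)
      batch_factors <- fac_batch[batch_idx, , drop = FALSE]
      batch_loadings <- matrix(stats::rnorm(n_genes * b, sd = p$batch_sd),
                               n_genes, b)
      batch_term <- batch_loadings %*% t(batch_factors)
    } else {
      # uniform shift on a random half of the genes: a purely global shift
      # would be absorbed by library-size rescaling and plant nothing
      shift <- stats::rnorm(p$n_batches, sd = p$batch_sd)
      batch_factors <- matrix(shift[batch_idx], n_samp, 1)
      batch_loadings <- matrix(as.numeric(
        sample(n_genes) <= n_genes / 2), n_genes, 1)
      batch_term <- batch_loadings %*% t(batch_factors)
    }
  } else {
    batch_factors <- matrix(0, n_samp, 1)
    batch_loadings <- matrix(0, n_genes, 1)
    batch_term <- matrix(0, n_genes, n_samp)
  }
  rownames(batch_factors) <- samples$sample_id

  # enrichment effects (log2, applied to enrichment libraries only)
  n_nad <- round(p$frac_nad * p$n_endogenous)
  true_nad <- if (n_nad > 0) sample(p$n_endogenous, n_nad) else integer(0)
  n_spk_en <- round(p$frac_spikein_enriched * p$n_spikein)
  spike_en <- if (n_spk_en > 0) p$n_endogenous + sample(p$n_spikein, n_spk_en)
              else integer(0)
  enrich_lfc <- numeric(n_genes)
  enrich_lfc[true_nad] <- p$enrichment_lfc
  enrich_lfc[spike_en] <- p$spike_enrichment_lfc
  enrich_lfc[n_genes - 1L] <- p$synthetic_nad_lfc  # SYN_NAD
  is_enr <- samples$assay == "enrichment"
  enrich_term <- outer(enrich_lfc, as.numeric(is_enr))

  # biological group effects, endogenous genes only
  group_effects <- matrix(0, n_genes, p$n_groups)
  n_grp_genes <- round(p$frac_group * p$n_endogenous)
  grp_genes <- if (n_grp_genes > 0 && p$n_groups > 1)
    sample(p$n_endogenous, n_grp_genes) else integer(0)
  if (length(grp_genes))
    group_effects[grp_genes, -1] <- stats::rnorm(
      length(grp_genes) * (p$n_groups - 1), sd = p$group_sd)
  grp_idx <- match(samples$group, paste0("G", seq_len(p$n_groups)))
  group_term <- group_effects[, grp_idx, drop = FALSE]

  log2_mu <- base_l2 + batch_term + enrich_term + group_term
  mu <- 2^log2_mu

  lib_sizes <- stats::runif(n_samp, p$lib_size_range[1], p$lib_size_range[2])
  mu <- sweep(mu, 2, lib_sizes / colSums(mu), "*")

  counts <- matrix(0, n_genes, n_samp, dimnames = list(gene_id, samples$sample_id))
  for (j in seq_len(n_samp)) {
    counts[, j] <- if (p$dispersion > 0)
      stats::rnbinom(n_genes, mu = mu[, j], size = 1 / p$dispersion)
    else stats::rpois(n_genes, lambda = mu[, j])
  }

  dataset <- sn_dataset(counts, samples, genes)
  truth <- list(
    true_nad_genes = gene_id[true_nad],
    enriched_spikeins = gene_id[spike_en],
    batch_factors = batch_factors,
    batch_loadings = batch_loadings,
    group_genes = gene_id[grp_genes],
    enrichment_lfc = stats::setNames(enrich_lfc, gene_id),
    lib_sizes = stats::setNames(lib_sizes, samples$sample_id),
    size_factors = stats::setNames(lib_sizes / exp(mean(log(lib_sizes))),
                                   samples$sample_id),
    params = params)
  list(dataset = dataset, truth = truth)
}

#' Score enrichment calls against simulation truth
#'
#' @param calls Data frame from [find_enrichment()] with columns `gene_id`
#'   and `is_nad_rna`; its gene universe must match the truth's endogenous
#'   genes.
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @return A one-row data.frame with `precision`, `recall`, `f1`, and the
#'   underlying confusion counts. Precision is `NaN` (flagged by
#'   `no_calls = TRUE`) when nothing is called.
#' @export
evaluate_against_truth <- function(calls, truth) {
  stopifnot(is.data.frame(calls), all(c("gene_id", "is_nad_rna") %in% names(calls)))
  universe <- grep("^ENDO", names(truth$enrichment_lfc), value = TRUE)
  endo <- calls[!(calls$gene_id %in% c("SYN_NAD", "SYN_M7G")), , drop = FALSE]
  if (!setequal(endo$gene_id, universe))
    stop("call gene universe does not match the simulation's endogenous genes")
  pos <- endo$gene_id[endo$is_nad_rna]
  true_set <- truth$true_nad_genes
  tp <- length(intersect(pos, true_set))
  fp <- length(setdiff(pos, true_set))
  fn <- length(setdiff(true_set, pos))
  precision <- if (length(pos) == 0) NaN else tp / (tp + fp)
  recall <- if (length(true_set) == 0) NaN else tp / (tp + fn)
  f1 <- if (is.nan(precision) || is.nan(recall) || (precision + recall) == 0)
    NaN else 2 * precision * recall / (precision + recall)
  data.frame(precision = precision, recall = recall, f1 = f1,
             tp = tp, fp = fp, fn = fn,
             no_calls = length(pos) == 0)
}
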