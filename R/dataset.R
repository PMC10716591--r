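#' Construct a spike-in enrichment dataset
#'
#' Bundles a gene-by-sample matrix of read counts with sample- and gene-level
#' metadata, the container consumed by every downstream step. The public
#' orientation is the bulk RNA-seq convention: genes as rows, samples as
#' columns.
#'
#' @param counts Non-negative integer matrix, genes x samples, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param samples data.frame with columns `sample_id`, `batch`, `assay`
#'   (exactly the two levels `"input"` and `"enrichment"`), `group`
#'   (biological covariate of interest) and `pair_id` linking each enrichment
#'   library to its input library. One row per sample.
#' @param genes data.frame with columns `gene_id`, `origin` (one of
#'   `"endogenous"`, `"spikein"`, `"synthetic_nad"`, `"synthetic_m7g"`),
#'   `biotype`, and optionally `length`. One row per gene.
#'
#' @return An object of class `sn_dataset`: a list with elements `counts`,
#'   `samples`, `genes`, with metadata rows reordered to match the matrix.
#' @export
sn_dataset <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have rownames (gene ids) and colnames (sample ids)")
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("negative values in `counts`")
  if (any(counts != round(counts)))
    stop("`counts` must contain integer read counts")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids in `counts` rownames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids in `counts` colnames")

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req_s <- c("sample_id", "batch", "assay", "group", "pair_id")
  if (!all(req_s %in% names(samples)))
    stop("`samples` must have columns: ", paste(req_s, collapse = ", "))
  req_g <- c("gene_id", "origin", "biotype")
  if (!all(req_g %in% names(genes)))
    stop("`genes` must have columns: ", paste(req_g, collapse = ", "))

  miss_s <- setdiff(colnames(counts), samples$sample_id)
  extra_s <- setdiff(samples$sample_id, colnames(counts))
  if (length(miss_s) || length(extra_s))
    stop("sample metadata does not match count columns; missing: [",
         paste(miss_s, collapse = ", "), "], unmatched: [",
         paste(extra_s, collapse = ", "), "]")
  miss_g <- setdiff(rownames(counts), genes$gene_id)
  extra_g <- setdiff(genes$gene_id, rownames(counts))
  if (length(miss_g) || length(extra_g))
    stop("gene metadata does not match count rows; missing: [",
         paste(utils::head(miss_g, 5), collapse = ", "), "], unmatched: [",
         paste(utils::head(extra_g, 5), collapse = ", "), "]")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id in metadata")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in metadata")

  bad_assay <- setdiff(unique(samples$assay), c("input", "enrichment"))
  if (length(bad_assay))
    stop("`assay` must be 'input' or 'enrichment'; found: ",
         paste(bad_assay, collapse = ", "))
  origins <- c("endogenous", "spikein", "synthetic_nad", "synthetic_m7g")
  bad_or <- setdiff(unique(genes$origin), origins)
  if (length(bad_or))
    stop("unknown gene origin: ", paste(bad_or, collapse = ", "))

  # align metadata to matrix order
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  rownames(samples) <- samples$sample_id
  rownames(genes) <- genes$gene_id

  structure(list(counts = counts, samples = samples, genes = genes),
            class = "sn_dataset")
}

#' @rdname sn_dataset
#' @param x An `sn_dataset`.
#' @param ... Unused.
#' @method print sn_dataset
#' @export
print.sn_dataset <- function(x, ...) {
  cat("sn_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  origins:",
      paste(names(table(x$genes$origin)), table(x$genes$origin),
            sep = "=", collapse = ", "), "\n")
  cat("  batches:", length(unique(x$samples$batch)),
      "| assay:", paste(names(table(x$samples$assay)),
                        table(x$samples$assay), sep = "=", collapse = ", "),
      "| groups:", length(unique(x$samples$group)), "\n")
  invisible(x)
}

#' @export
dim.sn_dataset <- function(x) dim(x$counts)

#' Subset a dataset by genes and/or samples
#'
#' @param x An `sn_dataset`.
#' @param i Gene index (ids, logical or integer).
#' @param j Sample index (ids, logical or integer).
#' @param ... Unused.
#' @param drop Ignored; dimensions are always kept.
#' @export
`[.sn_dataset` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  sn_dataset(x$counts[i, j, drop = FALSE],
             x$samples[j, , drop = FALSE],
             x$genes[i, , drop = FALSE])
}

#' Read a dataset from delimited or MatrixMarket files
#'
#' @param counts_path Path to the count matrix. For `format = "tsv"`/`"csv"`:
#'   header row of sample ids, first column gene ids. For `format = "mtx"`:
#'   a MatrixMarket file with sidecar label files `<stem>.rownames.txt` and
#'   `<stem>.colnames.txt` (one id per line).
#' @param samples_path,genes_path Paths to metadata tables in the same
#'   delimited format (tab for tsv/mtx, comma for csv) with the columns
#'   required by [sn_dataset()].
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return A validated [sn_dataset()].
#' @export
load_dataset <- function(counts_path, samples_path, genes_path,
                         format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  for (p in c(counts_path, samples_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sep <- if (format == "csv") "," else "\t"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(counts_path))
    stem <- sub("\\.mtx$", "", counts_path)
    rn <- readLines(paste0(stem, ".rownames.txt"))
    cn <- readLines(paste0(stem, ".colnames.txt"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MatrixMarket sidecar label files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    tab <- utils::read.table(counts_path, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("count matrix is not numeric: ", counts_path)
  }
  samples <- utils::read.table(samples_path, header = TRUE, sep = sep,
                               check.names = FALSE, stringsAsFactors = FALSE)
  genes <- utils::read.table(genes_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
  sn_dataset(m, samples, genes)
}

#' Write a dataset to delimited or MatrixMarket files
#'
#' Inverse of [load_dataset()]: `load_dataset(write_dataset(x, ...))` is the
#' identity on counts and metadata.
#'
#' @param dataset An `sn_dataset`.
#' @param dir Output directory (created if needed).
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return Invisibly, a named list of the three file paths written.
#' @export
write_dataset <- function(dataset, dir, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "sn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sep <- if (format == "csv") "," else "\t"
  ext <- if (format == "csv") "csv" else "tsv"
  if (format == "mtx") {
    cpath <- file.path(dir, "counts.mtx")
    Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), cpath)
    writeLines(rownames(dataset$counts), file.path(dir, "counts.rownames.txt"))
    writeLines(colnames(dataset$counts), file.path(dir, "counts.colnames.txt"))
  } else {
    cpath <- file.path(dir, paste0("counts.", ext))
    df <- data.frame(gene_id = rownames(dataset$counts),
                     dataset$counts, check.names = FALSE)
    utils::write.table(df, cpath, sep = sep, quote = FALSE, row.names = FALSE)
  }
  spath <- file.path(dir, paste0("samples.", ext))
  gpath <- file.path(dir, paste0("genes.", ext))
  utils::write.table(dataset$samples, spath, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$genes, gpath, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(list(counts = cpath, samples = spath, genes = gpath))
}

#' Log transform of read counts
#'
#' The framework's canonical transform: elementwise `log2(x + 1)`, so zero
#' counts map to zero and the transform is invertible via `2^y - 1`.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Transformed values, same shape as `x`.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log_transform requires non-negative input")
  log2(x + 1)
}
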