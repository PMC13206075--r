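#' Construct a count dataset
#'
#' The unit of one transcriptomic dataset: an integer gene x sample count
#' matrix plus a two-level group factor (`control`, `treatment`).
#'
#' @param counts non-negative integer matrix with unique gene rownames and
#'   sample colnames.
#' @param groups factor (or character) over the samples with levels
#'   `control` and `treatment`, each present with at least 2 samples.
#' @return An object of class `count_dataset`.
#' @export
count_dataset <- function(counts, groups) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop_field("counts", "must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_field("counts", "gene identifiers must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_field("counts", "must be non-negative integers")
  groups <- factor(as.character(groups), levels = c("control", "treatment"))
  if (length(groups) != ncol(counts) || anyNA(groups))
    stop_field("groups", "must label every sample as control or treatment")
  if (any(table(groups) < 2))
    stop_field("groups", "both group levels need >= 2 samples")
  if (is.null(names(groups))) names(groups) <- colnames(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, groups = groups), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples (%d control, %d treatment)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "control"), sum(x$groups == "treatment")))
  invisible(x)
}

#' Filter genes with low group-wise total counts
#'
#' Retains genes whose total count reaches `min_count` in at least one
#' group (`method = "union"`, the default reading of "either group"), or
#' in both groups (`method = "intersection"`). The filter operates on
#' group-total counts, not per-sample counts. Gene order is preserved.
#'
#' @param dataset a [count_dataset()].
#' @param min_count minimum group-total count (default 10).
#' @param method `"union"` (either group) or `"intersection"` (both).
#' @return The filtered [count_dataset()].
#' @export
filter_low_counts <- function(dataset, min_count = 10,
                              method = c("union", "intersection")) {
  stopifnot(inherits(dataset, "count_dataset"))
  method <- match.arg(method)
  ctl <- rowSums(dataset$counts[, dataset$groups == "control", drop = FALSE])
  trt <- rowSums(dataset$counts[, dataset$groups == "treatment", drop = FALSE])
  keep <- if (method == "union")
    ctl >= min_count | trt >= min_count
  else
    ctl >= min_count & trt >= min_count
  if (!any(keep)) stop("no genes pass filter", call. = FALSE)
  count_dataset(dataset$counts[keep, , drop = FALSE], dataset$groups)
}

#' Median-of-ratios size factors
#'
#' Reference expression per gene is the geometric mean over samples,
#' computed over genes with no zero count; each sample's factor is the
#' median across reference genes of its count over the reference.
#'
#' @param dataset a [count_dataset()] or count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(dataset) {
  counts <- if (inherits(dataset, "count_dataset")) dataset$counts else dataset
  ref_ok <- rowSums(counts == 0) == 0
  if (!any(ref_ok))
    stop(paste("no gene has nonzero counts in every sample;",
               "consider a pseudo-reference fallback"), call. = FALSE)
  ref <- exp(rowMeans(log(counts[ref_ok, , drop = FALSE])))
  apply(counts[ref_ok, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
}

#' Per-gene differential expression with moderated fold changes
#'
#' Normalizes by median-of-ratios size factors, computes a prior-count
#' moderated log2 fold change
#' `log2((mean normalized treatment + prior) / (mean normalized control +
#' prior))`, tests each gene with Welch's unequal-variance t-test on
#' `log2(normalized + prior)` values, and adjusts p-values by
#' Benjamini-Hochberg. The prior count moderates fold changes of
#' low-count genes toward zero (a simple stand-in for posterior
#' shrinkage estimators).
#'
#' @param dataset a [count_dataset()], already low-count filtered.
#' @param prior_count positive pseudo-count (default 2).
#' @param size_factors optional precomputed factors.
#' @return data.frame with columns `gene`, `baseMean`, `log2FoldChange`,
#'   `pvalue`, `padj` (column names fixed for interoperability).
#' @export
differential_expression <- function(dataset, prior_count = 2,
                                    size_factors = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  check_scalar(prior_count, "prior_count", positive = TRUE)
  if (any(table(dataset$groups) < 2))
    stop("each group needs >= 2 samples", call. = FALSE)
  sf <- if (is.null(size_factors)) estimate_size_factors(dataset)
        else size_factors
  norm <- sweep(dataset$counts, 2, sf, "/")
  is_trt <- dataset$groups == "treatment"
  mean_c <- rowMeans(norm[, !is_trt, drop = FALSE])
  mean_t <- rowMeans(norm[, is_trt, drop = FALSE])
  lfc <- log2((mean_t + prior_count) / (mean_c + prior_count))
  logn <- log2(norm + prior_count)
  x <- logn[, !is_trt, drop = FALSE]
  y <- logn[, is_trt, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  se2 <- vx / nx + vy / ny
  diff <- rowMeans(y) - rowMeans(x)
  # Welch-Satterthwaite df; degenerate zero-variance genes handled explicitly
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(diff[se2 == 0] == 0, 1, 0)
  data.frame(gene = rownames(dataset$counts),
             baseMean = rowMeans(norm),
             log2FoldChange = lfc,
             pvalue = p,
             padj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Strict thresholds: `|log2FC| > lfc_thresh` and `padj < alpha`.
#'
#' @param results data.frame from [differential_expression()].
#' @param lfc_thresh absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return Character vector of DEG identifiers.
#' @export
call_degs <- function(results, lfc_thresh = 1, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  keep <- abs(results$log2FoldChange) > lfc_thresh &
    !is.na(results$padj) & results$padj < alpha
  results$gene[keep]
}

#' Rank genes by log2 fold change
#'
#' Descending by `log2FoldChange`; ties broken by gene identifier in
#' lexicographic (C locale) order for determinism.
#'
#' @param results data.frame from [differential_expression()].
#' @return Named numeric vector (class `ranked_gene_list`): scores named
#'   by gene, sorted descending.
#' @export
rank_genes <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  if (anyDuplicated(results$gene))
    stop("duplicate gene identifiers in results", call. = FALSE)
  if (any(!is.finite(results$log2FoldChange)))
    stop("log2FoldChange must be finite for ranking", call. = FALSE)
  ord <- order(-results$log2FoldChange, results$gene, method = "radix")
  structure(stats::setNames(results$log2FoldChange[ord], results$gene[ord]),
            class = "ranked_gene_list")
}

#' Write a differential-expression table as TSV
#'
#' @param results data.frame from [differential_expression()].
#' @param path output path.
#' @export
write_de_table <- function(results, path) write_tsv(results, path)
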