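#' Select the most-altered genes of the drug profile
#'
#' The `ceiling(fraction * N)` genes with the largest absolute log2FC in
#' the drug profile; ties broken by gene identifier so the selection is
#' deterministic. The same subset is used for candidate and null
#' knockdowns, which keeps their correlations comparable.
#'
#' @param drug named log2FC vector of the drug profile.
#' @param fraction fraction of the universe to keep (default 0.2).
#' @return Character vector of selected genes (by decreasing |log2FC|).
#' @export
select_top_altered <- function(drug, fraction = 0.2) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop_field("fraction", "must lie in (0, 1]")
  n <- ceiling(fraction * length(drug))
  ord <- order(-abs(drug), names(drug), method = "radix")
  names(drug)[ord][seq_len(n)]
}

#' Pearson concordance between knockdown and drug profiles
#'
#' Sample Pearson correlation of the two log2FC vectors restricted to
#' the given gene subset.
#'
#' @param kd knockdown profile (named log2FC vector).
#' @param drug drug profile over the same universe.
#' @param genes gene subset (>= 3 genes, covered by both profiles).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   restricted vector has zero variance.
#' @export
pcc_concordance <- function(kd, drug, genes) {
  if (length(genes) < 3)
    stop("need >= 3 genes for a correlation", call. = FALSE)
  if (!all(genes %in% names(kd)) || !all(genes %in% names(drug)))
    stop("both profiles must cover the gene subset", call. = FALSE)
  x <- as.numeric(kd[genes]); y <- as.numeric(drug[genes])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a restricted profile; PCC undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Random-gene null distribution of knockdown-drug concordance
#'
#' Samples `n_null` genes without replacement from the eligible pool
#' (candidates must already be excluded), simulates each knockdown, and
#' computes its PCC with the drug profile on the same top-fraction gene
#' subset used for the candidates.
#'
#' @param model a [fit_reference_model()] result (ignored when `kd_fun`
#'   is supplied).
#' @param drug drug profile.
#' @param n_null number of random genes (default 100).
#' @param fraction top-altered fraction (default 0.2).
#' @param seed integer seed for the gene draw.
#' @param eligible pool of genes to sample from (candidates excluded;
#'   typically the expressed, filter-passing genes).
#' @param kd_fun optional function `gene -> profile` overriding
#'   [simulate_knockdown()] (e.g. externally supplied profiles).
#' @param primary_log2fc knockdown strength passed to
#'   [simulate_knockdown()].
#' @param basis `"drug"` (default): one top-fraction subset ranked by the
#'   drug profile, shared by every knockdown; `"union"`: per-pair union
#'   of the drug's and the knockdown's own top-fraction subsets.
#' @return Named numeric vector of null PCCs (length `n_null`; `NA`
#'   entries flag zero-variance profiles).
#' @export
random_null <- function(model, drug, n_null = 100, fraction = 0.2,
                        seed = 1, eligible, kd_fun = NULL,
                        primary_log2fc = -2,
                        basis = c("drug", "union")) {
  basis <- match.arg(basis)
  check_scalar(n_null, "n_null", positive = TRUE, integer = TRUE)
  if (length(eligible) < n_null)
    stop(sprintf("eligible pool (%d) smaller than n_null (%d)",
                 length(eligible), n_null), call. = FALSE)
  if (is.null(kd_fun))
    kd_fun <- function(g) simulate_knockdown(model, g, primary_log2fc)
  picked <- with_seed(seed, sample(eligible, n_null))
  out <- vapply(picked, function(g) {
    kd <- kd_fun(g)
    suppressWarnings(
      pcc_concordance(kd, drug, pair_subset(kd, drug, fraction, basis)))
  }, numeric(1))
  stats::setNames(out, picked)
}

# Gene subset on which a knockdown-drug pair is correlated.
pair_subset <- function(kd, drug, fraction, basis) {
  if (basis == "drug") select_top_altered(drug, fraction)
  else union(select_top_altered(drug, fraction),
             select_top_altered(kd, fraction))
}

# Exact null distribution of the rank-sum W of the smaller sample:
# number of size-n1 subsets of ranks 1..(n1+n2) with each possible sum.
ranksum_count <- function(n1, n2) {
  n <- n1 + n2
  wmax <- sum(seq(n2 + 1, n))
  g <- matrix(0, n1 + 1, wmax + 1)
  g[1, 1] <- 1
  for (r in seq_len(n)) {
    kk <- min(r, n1)
    for (k in seq(kk, 1)) {
      idx <- seq_len(wmax + 1 - r)
      g[k + 1, idx + r] <- g[k + 1, idx + r] + g[k, idx]
    }
  }
  g[n1 + 1, ]          # counts for W = 0..wmax (offset: index w+1)
}

#' Unpaired two-sided Wilcoxon rank-sum comparison against the null
#'
#' Compares the candidate PCC sample with the random-gene null sample.
#' When the smaller sample has at most 20 observations and there are no
#' ties, the p-value is computed by exact enumeration of the rank-sum
#' distribution; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param candidate_pccs numeric vector of candidate concordances.
#' @param null_sample numeric vector of null concordances.
#' @return Two-sided p-value.
#' @export
compare_to_null <- function(candidate_pccs, null_sample) {
  x <- candidate_pccs[!is.na(candidate_pccs)]
  y <- null_sample[!is.na(null_sample)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])                    # rank sum of the candidates
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && min(n1, n2) <= 20) {
    # exact: orient the DP on the smaller sample, U is symmetric
    if (n1 <= n2) {
      cnt <- ranksum_count(n1, n2)
      w_obs <- W
      off <- n1 * (n1 + 1) / 2
    } else {
      cnt <- ranksum_count(n2, n1)
      w_obs <- sum(r[-seq_len(n1)])
      off <- n2 * (n2 + 1) / 2
    }
    total <- sum(cnt)
    w_idx <- round(w_obs) + 1L
    lower <- sum(cnt[seq_len(w_idx)]) / total
    upper <- sum(cnt[seq(w_idx, length(cnt))]) / total
    return(min(1, 2 * min(lower, upper)))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' AUROC via the Mann-Whitney U statistic
#'
#' `AUROC = U / (n_pos * n_neg)`, computed from mean ranks so tied
#' scores count one half. Equals the probability that a random positive
#' outscores a random negative.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels.
#' @return AUROC in `[0, 1]`, or `NA` (with warning) if only one class
#'   is present.
#' @export
auroc_ustat <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("single-class labels; AUROC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pathway-level AUROC of knockdown vs drug enrichment
#'
#' Uses the drug's pathway alterations as ground-truth labels (pathways
#' with drug enrichment `pval < alpha` and NES sign matching
#' `direction` are positives) and the knockdown's signed NES as the
#' prediction score (negated for `direction = "down"` so that a larger
#' score always predicts a positive label).
#'
#' @param drug_enrichment [preranked_gsea()] table for the drug
#'   profile.
#' @param kd_enrichment [preranked_gsea()] table for the knockdown
#'   profile, sharing the pathway namespace.
#' @param direction `"up"` or `"down"`.
#' @param alpha drug-enrichment significance threshold (default 0.05).
#' @return List with `auroc`, `n_pos`, `n_neg`, `direction` (`auroc` is
#'   `NA`, flagged by a warning, when only one label class exists).
#' @export
pathway_auroc <- function(drug_enrichment, kd_enrichment,
                          direction = c("up", "down"), alpha = 0.05) {
  direction <- match.arg(direction)
  shared <- intersect(drug_enrichment$pathway, kd_enrichment$pathway)
  if (length(shared) == 0)
    stop("no shared pathways between drug and knockdown enrichment",
         call. = FALSE)
  dr <- drug_enrichment[match(shared, drug_enrichment$pathway), ]
  kd <- kd_enrichment[match(shared, kd_enrichment$pathway), ]
  sgn <- if (direction == "up") 1 else -1
  labels <- dr$pval < alpha & sgn * dr$NES > 0
  scores <- sgn * kd$NES
  auc <- auroc_ustat(scores, labels)
  list(auroc = auc, n_pos = sum(labels), n_neg = sum(!labels),
       direction = direction)
}

#' Assemble a knockdown-drug concordance report
#'
#' Runs the full transcriptome-level validation for a set of candidate
#' genes: top-fraction PCC per candidate, a random-gene null of size
#' `n_null`, and the rank-sum comparison of the candidate group against
#' the null.
#'
#' @param model a [fit_reference_model()] result (or `NULL` with
#'   `kd_fun`).
#' @param drug drug profile.
#' @param candidates candidate target genes.
#' @param eligible eligible pool for the null (candidates are removed
#'   internally).
#' @param n_null null size (default 100).
#' @param fraction top-altered fraction (default 0.2).
#' @param seed integer seed.
#' @param kd_fun optional gene -> profile function (see
#'   [random_null()]).
#' @param primary_log2fc knockdown strength (default -2).
#' @param basis top-altered subset basis, `"drug"` or `"union"` (see
#'   [random_null()]).
#' @return List of class `concordance_report`: `candidate_pcc` (named),
#'   `null_pcc`, `ranksum_p`, and a `meta` record of the settings.
#' @export
concordance_report <- function(model, drug, candidates, eligible,
                               n_null = 100, fraction = 0.2, seed = 1,
                               kd_fun = NULL, primary_log2fc = -2,
                               basis = c("drug", "union")) {
  basis <- match.arg(basis)
  eligible <- setdiff(eligible, candidates)
  if (is.null(kd_fun))
    kd_fun <- function(g) simulate_knockdown(model, g, primary_log2fc)
  cand <- vapply(candidates, function(g) {
    kd <- kd_fun(g)
    suppressWarnings(
      pcc_concordance(kd, drug, pair_subset(kd, drug, fraction, basis)))
  }, numeric(1))
  null <- random_null(model, drug, n_null = n_null, fraction = fraction,
                      seed = seed, eligible = eligible, kd_fun = kd_fun,
                      primary_log2fc = primary_log2fc, basis = basis)
  p <- compare_to_null(cand, null)
  structure(list(
    candidate_pcc = stats::setNames(cand, candidates),
    null_pcc = null,
    ranksum_p = p,
    meta = list(fraction = fraction, n_null = n_null, seed = seed,
                primary_log2fc = primary_log2fc, basis = basis,
                n_top_genes = length(select_top_altered(drug, fraction)))),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance_report: %d candidate(s), null n = %d, rank-sum p = %.3g\n",
    length(x$candidate_pcc), length(x$null_pcc), x$ranksum_p))
  print(round(x$candidate_pcc, 3))
  invisible(x)
}

#' Write a concordance report as JSON plus flat TSVs
#'
#' @param report a [concordance_report()] result.
#' @param dir output directory (created if needed).
#' @param auroc_table optional data.frame of pathway AUROCs (columns
#'   `collection`, `direction`, `candidate`, `auroc`, `n_pos`,
#'   `n_neg`).
#' @export
write_concordance_report <- function(report, dir, auroc_table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(candidate = names(report$candidate_pcc),
                       pcc = as.numeric(report$candidate_pcc),
                       stringsAsFactors = FALSE),
            file.path(dir, "candidate_pcc.tsv"))
  write_tsv(data.frame(gene = names(report$null_pcc),
                       pcc = as.numeric(report$null_pcc),
                       stringsAsFactors = FALSE),
            file.path(dir, "null_pcc.tsv"))
  if (!is.null(auroc_table))
    write_tsv(auroc_table, file.path(dir, "auroc.tsv"))
  jsonlite::write_json(
    list(candidate_pcc = as.list(report$candidate_pcc),
         ranksum_p = report$ranksum_p,
         null_summary = list(n = length(report$null_pcc),
                             mean = mean(report$null_pcc, na.rm = TRUE),
                             q95 = unname(stats::quantile(report$null_pcc,
                                                          0.95,
                                                          na.rm = TRUE))),
         meta = report$meta),
    file.path(dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
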