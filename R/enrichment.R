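#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: at a member ("hit") the running sum increases by
#' `|score|^weight / sum(|score|^weight over members)`, at a non-member it
#' decreases by `1 / (N - Nh)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero; on ties the first such
#' position is taken.
#'
#' @param ranked a [rank_genes()] result (named scores, sorted
#'   descending).
#' @param members character vector of member genes.
#' @param weight score weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov walk).
#' @return List with `ES` (in `[-1, 1]`) and `peak_index`.
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  scores <- as.numeric(ranked)
  genes <- names(ranked)
  N <- length(scores)
  hits <- genes %in% members
  Nh <- sum(hits)
  if (Nh == 0) stop("no set members in the ranked universe", call. = FALSE)
  if (Nh == N) stop("set covers the whole ranked universe", call. = FALSE)
  w <- abs(scores)^weight
  NR <- sum(w[hits])
  incr <- if (NR > 0) w * hits / NR else hits / Nh
  decr <- (!hits) / (N - Nh)
  run <- cumsum(incr - decr)
  peak <- which.max(abs(run))          # first position attaining the max
  list(ES = run[peak], peak_index = peak)
}

#' Leading-edge gene subset
#'
#' For a positive enrichment score, the set members at ranks up to and
#' including the running-sum peak; for a negative score, the members at
#' ranks from the peak onward. Returned in rank order.
#'
#' @param ranked a [rank_genes()] result.
#' @param members member genes of the set.
#' @param ES enrichment score from [enrichment_score()].
#' @param peak_index peak position from [enrichment_score()].
#' @return Ordered character vector of leading-edge genes.
#' @export
leading_edge <- function(ranked, members, ES, peak_index) {
  genes <- names(ranked)
  if (ES == 0) {
    warning("ES is zero; empty leading edge")
    return(character(0))
  }
  idx <- if (ES > 0) seq_len(peak_index)
         else seq(peak_index, length(genes))
  genes[idx][genes[idx] %in% members]
}

# ES of one member-rank set from hit positions only: between hits the walk
# is linear, so extremes occur right after a hit (A) or just before one (B).
es_from_hit_ranks <- function(r, absw, N) {
  m <- length(r)
  wh <- absw[r]
  NR <- sum(wh)
  H <- if (NR > 0) cumsum(wh) / NR else seq_len(m) / m
  d <- 1 / (N - m)
  A <- H - (r - seq_len(m)) * d
  B <- c(0, H[-m]) - (r - seq_len(m)) * d
  top <- max(A); bot <- min(B)
  if (top >= -bot) top else bot
}

#' Pre-ranked gene-set enrichment with gene-permutation null
#'
#' For each set: the enrichment score and leading edge, a Monte-Carlo
#' permutation p-value from `n_perm` random member sets of equal size
#' drawn from the ranked universe
#' (`p = (1 + #same-sign permuted |ES| >= |ES|) / (1 + #same-sign
#' permutations)`, so p is never exactly zero), a normalized score
#' `NES = ES / mean(|same-sign permuted ES|)`, and Benjamini-Hochberg
#' adjustment across the collection. Deterministic under a fixed seed.
#'
#' @param ranked a [rank_genes()] result.
#' @param collection named list of member-gene vectors (see
#'   [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @param weight score weight exponent passed to [enrichment_score()].
#' @param min_size sets smaller than this after intersection with the
#'   universe are skipped with a message (default 2).
#' @return data.frame with columns `pathway`, `size`, `ES`, `NES`,
#'   `pval`, `padj`, `direction`, `leadingEdge` (comma-joined, rank
#'   order).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000, seed = 1,
                           weight = 1, min_size = 2) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  check_scalar(n_perm, "n_perm", positive = TRUE, integer = TRUE)
  if (n_perm < 100) stop_field("n_perm", "must be >= 100")
  genes <- names(ranked)
  N <- length(genes)
  absw <- abs(as.numeric(ranked))^weight
  rows <- with_seed(seed, {
    lapply(names(collection), function(nm) {
      members <- intersect(collection[[nm]], genes)
      m <- length(members)
      if (m < min_size || m >= N) {
        message(sprintf("skipping set '%s': size %d outside [%d, %d]",
                        nm, m, min_size, N - 1L))
        return(NULL)
      }
      es <- enrichment_score(ranked, members, weight)
      le <- if (es$ES == 0) character(0)
            else leading_edge(ranked, members, es$ES, es$peak_index)
      perm <- vapply(seq_len(n_perm), function(i)
        es_from_hit_ranks(sort(sample.int(N, m)), absw, N), numeric(1))
      if (es$ES == 0) {
        pval <- 1; nes <- 0
      } else {
        same <- if (es$ES > 0) perm > 0 else perm < 0
        pval <- (1 + sum(abs(perm[same]) >= abs(es$ES))) / (1 + sum(same))
        nes <- if (any(same)) es$ES / mean(abs(perm[same])) else NA_real_
      }
      data.frame(pathway = nm, size = m, ES = es$ES, NES = nes,
                 pval = pval,
                 direction = if (es$ES >= 0) "up" else "down",
                 leadingEdge = paste(le, collapse = ","),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable sets in collection", call. = FALSE)
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out[, c("pathway", "size", "ES", "NES", "pval", "padj",
          "direction", "leadingEdge")]
}

#' Split the comma-joined leading-edge column into a named list
#'
#' @param result data.frame from [preranked_gsea()].
#' @return Named list (by pathway) of leading-edge gene vectors.
#' @export
leading_edge_list <- function(result) {
  le <- strsplit(result$leadingEdge, ",", fixed = TRUE)
  le <- lapply(le, function(x) x[nzchar(x)])
  stats::setNames(le, result$pathway)
}

#' Hypergeometric over-representation analysis
#'
#' Exact upper-tail hypergeometric p-value for the overlap of a query
#' gene set with each collection set, Benjamini-Hochberg adjusted.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param collection named list of member-gene vectors.
#' @param universe background gene universe.
#' @return data.frame with columns `set`, `size`, `overlap`, `p`, `padj`.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  if (length(query) == 0) stop("empty query gene set", call. = FALSE)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  query <- unique(query)
  N <- length(unique(universe))
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no collection set overlaps the universe", call. = FALSE)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member genes.
#'
#' @param path path to the GMT file.
#' @return Named list of member-gene vectors, with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT lines (need name, description, >=1 member): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection named list of member-gene vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
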