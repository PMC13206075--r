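#' Consensus pathways across datasets
#'
#' A pathway is a consensus pathway in a direction when it is
#' significantly enriched (`pval < alpha`) with that direction of
#' regulation in at least `ceiling(min_frac * K)` of the K datasets
#' (with K = 7 and the default 50% rule this threshold is 4). A pathway
#' is never emitted in both directions: the direction with the larger
#' supporting count wins, and an exact tie emits neither (with a
#' warning).
#'
#' @param results named list (by dataset) of [preranked_gsea()] tables
#'   sharing a pathway namespace.
#' @param alpha per-dataset enrichment significance threshold (default
#'   0.05).
#' @param min_frac minimum supporting fraction of datasets (default 0.5).
#' @return data.frame with columns `pathway`, `direction`, `support`,
#'   `K`, `datasets` (semicolon-joined contributing dataset ids).
#' @export
consensus_pathways <- function(results, alpha = 0.05, min_frac = 0.5) {
  if (!is.list(results) || length(results) < 2 || is.null(names(results)))
    stop("results must be a named list of >= 2 enrichment tables",
         call. = FALSE)
  K <- length(results)
  thr <- ceiling(min_frac * K)
  pathways <- sort(unique(unlist(lapply(results, `[[`, "pathway"))))
  rows <- lapply(pathways, function(pw) {
    sig <- lapply(names(results), function(ds) {
      r <- results[[ds]]
      row <- r[r$pathway == pw & r$pval < alpha, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      list(ds = ds, dir = row$direction[1])
    })
    sig <- Filter(Negate(is.null), sig)
    up <- vapply(sig, function(s) s$dir == "up", logical(1))
    ds_up <- vapply(sig[up], `[[`, character(1), "ds")
    ds_dn <- vapply(sig[!up], `[[`, character(1), "ds")
    n_up <- length(ds_up); n_dn <- length(ds_dn)
    if (max(n_up, n_dn) < thr) return(NULL)
    if (n_up >= thr && n_dn >= thr && n_up == n_dn) {
      warning(sprintf("pathway '%s': directional tie (%d up, %d down); omitted",
                      pw, n_up, n_dn))
      return(NULL)
    }
    if (n_up >= n_dn)
      data.frame(pathway = pw, direction = "up", support = n_up, K = K,
                 datasets = paste(ds_up, collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(pathway = pw, direction = "down", support = n_dn, K = K,
                 datasets = paste(ds_dn, collapse = ";"),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(0), direction = character(0),
                      support = integer(0), K = integer(0),
                      datasets = character(0), stringsAsFactors = FALSE)
  out
}

#' Leading-edge occurrence frequencies
#'
#' For each consensus pathway, the contributing datasets are those where
#' the pathway was significant in the consensus direction; each member
#' gene's frequency for that pathway is the fraction of those datasets
#' whose leading edge contains the gene. Per gene, the maximum frequency
#' over its pathways is reported (a gene is core if it is core for any
#' consensus pathway).
#'
#' @param consensus data.frame from [consensus_pathways()].
#' @param results the same named list of enrichment tables.
#' @return data.frame with columns `gene`, `frequency`,
#'   `n_contributing`, `pathways` (semicolon-joined).
#' @export
leading_edge_frequency <- function(consensus, results) {
  if (nrow(consensus) == 0)
    stop("consensus table is empty", call. = FALSE)
  le_by_ds <- lapply(results, leading_edge_list)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(consensus))) {
    pw <- consensus$pathway[i]
    contributing <- strsplit(consensus$datasets[i], ";", fixed = TRUE)[[1]]
    denom <- length(contributing)
    tab <- table(unlist(lapply(contributing, function(ds) {
      le <- le_by_ds[[ds]][[pw]]
      if (is.null(le)) character(0) else unique(le)
    })))
    for (g in names(tab)) {
      freq <- as.numeric(tab[[g]]) / denom
      cur <- if (exists(g, envir = acc)) get(g, envir = acc) else NULL
      if (is.null(cur) || freq > cur$frequency) {
        pws <- if (is.null(cur)) pw else union(cur$pathways, pw)
        assign(g, list(frequency = freq, n = as.integer(tab[[g]]),
                       pathways = pws), envir = acc)
      } else {
        cur$pathways <- union(cur$pathways, pw)
        assign(g, cur, envir = acc)
      }
    }
  }
  genes <- sort(ls(acc))
  out <- do.call(rbind, lapply(genes, function(g) {
    v <- get(g, envir = acc)
    data.frame(gene = g, frequency = v$frequency,
               n_contributing = v$n,
               pathways = paste(sort(v$pathways), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Core leading-edge genes
#'
#' Genes whose leading-edge occurrence frequency is strictly greater
#' than `min_freq` (default 0.5: present in more than half of the
#' datasets where their pathway was significant).
#'
#' @param table data.frame from [leading_edge_frequency()].
#' @param min_freq strict lower frequency bound (default 0.5).
#' @return Sorted character vector of core gene identifiers.
#' @export
core_leading_edge_genes <- function(table, min_freq = 0.5) {
  stopifnot(is.data.frame(table))
  sort(table$gene[table$frequency > min_freq])
}
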