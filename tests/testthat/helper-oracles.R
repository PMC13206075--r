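# Independent oracles and shared fixtures used across test files.

# Step-by-step running-sum walk: the enrichment-score oracle, kept
# deliberately loop-based and independent of the package's vectorized path.
oracle_es_walk <- function(scores, genes, members, weight = 1) {
  N <- length(scores)
  hit <- genes %in% members
  NR <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  best_i <- 0L
  values <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (NR > 0) abs(scores[i])^weight / NR else 1 / sum(hit)
    } else {
      -1 / (N - sum(hit))
    }
    values[i] <- run
    if (abs(run) > abs(best)) {
      best <- run
      best_i <- i
    }
  }
  list(ES = best, peak_index = best_i, values = values)
}

# Brute-force AUROC: average over all positive-negative pairs, ties half.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Hand-rolled Benjamini-Hochberg step-up, independent of p.adjust.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exact two-sided rank-sum p by full enumeration of label assignments
# (feasible for n1 + n2 <= 10).
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(all_v), n1)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  lower <- mean(sums <= obs)
  upper <- mean(sums >= obs)
  min(1, 2 * min(lower, upper))
}

# Median-of-ratios oracle, written directly from the formula.
oracle_size_factors <- function(counts) {
  ref_ok <- apply(counts, 1, function(x) all(x > 0))
  ref <- apply(counts[ref_ok, , drop = FALSE], 1,
               function(x) exp(mean(log(x))))
  apply(counts[ref_ok, , drop = FALSE], 2,
        function(col) median(col / ref))
}

# Small toy count dataset with hand-set values, 5 genes x 4 samples.
toy_counts <- function() {
  m <- matrix(c(
    0,  0, 12,  5,    # trt total 17, ctl total 0
    0,  0,  0,  0,    # all zero
    6,  3,  2,  1,    # ctl 9, trt 3
    20, 15, 30, 25,   # both high
    4,  5,  3,  2     # ctl 9, trt 5
  ), nrow = 5, byrow = TRUE,
  dimnames = list(paste0("g", 1:5),
                  c("c1", "c2", "t1", "t2")))
  m
}

toy_dataset <- function(m = NULL) {
  if (is.null(m)) m <- toy_counts()
  groups <- factor(c("control", "control", "treatment", "treatment"),
                   levels = c("control", "treatment"))
  names(groups) <- colnames(m)
  count_dataset(m, groups)
}

# Build a minimal enrichment table row-by-row for consensus tests.
toy_enrichment <- function(pathways, pvals, ness, leading = NULL) {
  if (is.null(leading)) leading <- rep("", length(pathways))
  data.frame(pathway = pathways, size = 10L, ES = sign(ness) * 0.5,
             NES = ness, pval = pvals, padj = pvals,
             direction = ifelse(ness >= 0, "up", "down"),
             leadingEdge = leading, stringsAsFactors = FALSE)
}

# Memoized small simulated study shared by several test files.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, cfg) {
  if (!exists(key, envir = .sim_cache))
    assign(key, simulate_study(cfg), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

small_sim <- function() {
  cached_sim("small", simulation_config(
    n_datasets = 3, n_genes = 400, n_samples_per_group = 5,
    n_gene_sets = 15, n_active_sets = 4, consensus_support = 2,
    set_size_range = c(8, 20), n_decoys = 40, seed = 42))
}

docking_fixture <- function() {
  read_docking_table(system.file("extdata",
                                 "teriflunomide_docking_affinities.tsv",
                                 package = "dedtarget"))
}
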