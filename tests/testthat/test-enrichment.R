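ranked_from <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  rank_genes(data.frame(gene = genes, baseMean = 1,
                        log2FoldChange = scores, pvalue = 0.5, padj = 0.5,
                        stringsAsFactors = FALSE))
}

test_that("enrichment score matches the running-sum oracle on toy cases", {
  # single member at the top of the list: full hit mass before any miss
  r <- ranked_from(c(3, 2, 1, -1, -2))
  es <- enrichment_score(r, "g01")
  expect_equal(es$ES, 1)
  expect_equal(es$peak_index, 1L)
  expect_identical(leading_edge(r, "g01", es$ES, es$peak_index), "g01")
  # 6-gene list, 2-member set: step-by-step oracle
  scores <- c(2.5, 1.2, 0.8, -0.3, -1.1, -2.0)
  r6 <- ranked_from(scores)
  members <- c("g02", "g05")
  es6 <- enrichment_score(r6, members)
  o <- oracle_es_walk(sort(scores, decreasing = TRUE), names(r6), members)
  expect_equal(es6$ES, o$ES)
  expect_equal(es6$peak_index, o$peak_index)
  le <- leading_edge(r6, members, es6$ES, es6$peak_index)
  if (o$ES > 0) {
    expect_identical(le,
                     names(r6)[seq_len(o$peak_index)][
                       names(r6)[seq_len(o$peak_index)] %in% members])
  }
  # degenerate sets are rejected
  expect_error(enrichment_score(r6, "not_here"), "no set members")
  expect_error(enrichment_score(r6, names(r6)), "whole ranked universe")
})

test_that("ES is antisymmetric under score negation with reversed order", {
  scores <- c(2.2, 1.5, 0.4, -0.6, -1.3, -2.1, 0.9, -0.2)
  genes <- sprintf("g%02d", 1:8)
  members <- c("g02", "g06", "g07")
  r_fwd <- ranked_from(scores, genes)
  r_rev <- ranked_from(-scores, genes)
  es_f <- enrichment_score(r_fwd, members)
  es_r <- enrichment_score(r_rev, members)
  expect_equal(es_f$ES, -es_r$ES)
})

test_that("ES stays in [-1, 1] and is scale-invariant at weight 0", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    scores <- rnorm(n)
    r <- ranked_from(scores, sprintf("x%02d", 1:n))
    members <- sample(names(r), sample(2:3, 1))
    es <- enrichment_score(r, members)
    expect_true(abs(es$ES) <= 1 + 1e-12)
    # monotone rescaling leaves the weight-0 walk unchanged
    r2 <- ranked_from(sort(scores, decreasing = TRUE) * 7 + 0,
                      names(r))
    expect_equal(enrichment_score(r, members, weight = 0)$ES,
                 enrichment_score(r2, members, weight = 0)$ES)
  }
})

test_that("vectorized ES agrees with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  for (i in 1:10) {
    n <- 40
    scores <- sort(rnorm(n), decreasing = TRUE)
    genes <- sprintf("g%02d", 1:n)
    r <- ranked_from(scores, genes)
    members <- sample(genes, 6)
    ours <- enrichment_score(r, members)$ES
    theirs <- fgsea::calcGseaStat(setNames(as.numeric(r), names(r)),
                                  which(names(r) %in% members),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("preranked GSEA is seeded, bounded, and recovers a planted set", {
  sim <- small_sim()
  ds <- sim$datasets[[1]]
  res <- differential_expression(filter_low_counts(ds))
  r <- rank_genes(res)
  g1 <- preranked_gsea(r, sim$gene_sets, n_perm = 200, seed = 5)
  g2 <- preranked_gsea(r, sim$gene_sets, n_perm = 200, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(g1$pval > 0 & g1$pval <= 1))
  expect_true(all(sign(g1$NES) == sign(g1$ES) | g1$ES == 0))
  expect_true(all(g1$direction == ifelse(g1$ES >= 0, "up", "down")))
  # leading edges are members on the peak side
  les <- leading_edge_list(g1)
  for (pw in names(les))
    expect_true(all(les[[pw]] %in% sim$gene_sets[[pw]]))
  # planted sets supported in this dataset come out significant with the
  # planted direction
  planted <- sim$truth$active_sets
  here <- vapply(strsplit(planted$datasets, ";"),
                 function(d) names(sim$datasets)[1] %in% d, logical(1))
  for (i in which(here)) {
    row <- g1[g1$pathway == planted$set[i], ]
    expect_lt(row$pval, 0.05)
    expect_identical(row$direction, planted$direction[i])
  }
  expect_error(preranked_gsea(r, sim$gene_sets, n_perm = 10), "n_perm")
})

test_that("permutation p-values converge with more permutations", {
  sim <- small_sim()
  r <- rank_genes(differential_expression(filter_low_counts(
    sim$datasets[[2]])))
  coll <- sim$gene_sets[5:8]
  p1 <- preranked_gsea(r, coll, n_perm = 400, seed = 1)$pval
  p2 <- preranked_gsea(r, coll, n_perm = 800, seed = 2)$pval
  # binomial MC error bound at p ~ 0.5 is ~0.025; allow 4 sd
  expect_true(all(abs(p1 - p2) < 4 * sqrt(0.25 / 400) + 0.01))
})

test_that("hypergeometric ORA matches the exact tail sum", {
  universe <- sprintf("u%03d", 1:100)
  collection <- list(S = universe[1:10])
  # overlap N=100, K=10, n=10, k=5: direct summation oracle
  query <- c(universe[1:5], universe[21:25])
  out <- ora_hypergeometric(query, collection, universe)
  p_manual <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)))
  expect_equal(out$p, p_manual, tolerance = 1e-12)
  expect_equal(out$overlap, 5)
  # disjoint query: upper tail at overlap 0 is 1
  out0 <- ora_hypergeometric(universe[51:60], collection, universe)
  expect_equal(out0$p, 1)
  # fully contained query attains the minimal p for these parameters
  outf <- ora_hypergeometric(universe[1:10], collection, universe)
  expect_equal(outf$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_error(ora_hypergeometric(character(0), collection, universe),
               "empty query")
  expect_error(ora_hypergeometric("absent", collection, universe),
               "subset")
})

test_that("GMT reader rejects malformed lines and round-trips content", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2", "BROKEN_LINE"), path)
  expect_error(read_gmt(path), "malformed GMT lines.*2")
  coll <- list(A = c("g1", "g2"), B = c("g3", "g4", "g5"))
  write_gmt(coll, path, descriptions = c(A = "first", B = "second"))
  back <- read_gmt(path)
  expect_identical(lapply(back, identity), coll)
  expect_identical(attr(back, "descriptions")[["A"]], "first")
})
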