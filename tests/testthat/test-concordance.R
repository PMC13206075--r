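test_that("top-altered selection is sized and ordered deterministically", {
  drug <- setNames(c(0.1, -3, 2, 0.5, -0.2, 1, -1.5, 0.05, 0.7, -0.9),
                   sprintf("g%02d", 1:10))
  expect_identical(select_top_altered(drug, 0.2), c("g02", "g03"))
  expect_equal(length(select_top_altered(drug, 1)), 10)
  # uniform |log2FC|: lexicographic tie rule
  flat <- setNames(rep(1, 5), c("e", "c", "a", "d", "b"))
  expect_identical(select_top_altered(flat, 0.4), c("a", "b"))
  expect_error(select_top_altered(drug, 0), "fraction")
})

test_that("PCC concordance matches the closed-form correlation", {
  genes <- paste0("g", 1:5)
  kd <- setNames(c(1, 2, 3, 4, 5), genes)
  drug <- setNames(c(2, 1, 4, 3, 6), genes)
  r_manual <- sum((kd - mean(kd)) * (drug - mean(drug))) /
    sqrt(sum((kd - mean(kd))^2) * sum((drug - mean(drug))^2))
  expect_equal(pcc_concordance(kd, drug, genes), r_manual)
  expect_equal(pcc_concordance(drug, drug, genes), 1)
  expect_equal(pcc_concordance(setNames(-drug, genes), drug, genes), -1)
  # invariant to positive affine transforms
  expect_equal(pcc_concordance(setNames(3 * kd + 7, genes), drug, genes),
               r_manual)
  expect_warning(
    flatr <- pcc_concordance(setNames(rep(1, 5), genes), drug, genes),
    "zero variance")
  expect_true(is.na(flatr))
  expect_error(pcc_concordance(kd[1:2], drug, genes), "cover")
})

test_that("random null is seeded, exhaustive at the boundary, and near zero", {
  sim <- small_sim()
  drug <- sim$profiles[["drug"]]
  kd_fun <- function(g) sim$profiles[[paste0("KD:", g)]]
  decoys <- sim$truth$decoy_genes
  n1 <- random_null(NULL, drug, n_null = 20, seed = 8, eligible = decoys,
                    kd_fun = kd_fun)
  n2 <- random_null(NULL, drug, n_null = 20, seed = 8, eligible = decoys,
                    kd_fun = kd_fun)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1, na.rm = TRUE)), 0.08)
  # n_null = |eligible| enumerates every decoy exactly once
  full <- random_null(NULL, drug, n_null = length(decoys), seed = 1,
                      eligible = decoys, kd_fun = kd_fun)
  expect_setequal(names(full), decoys)
  expect_error(random_null(NULL, drug, n_null = 1000, seed = 1,
                           eligible = decoys, kd_fun = kd_fun),
               "smaller than n_null")
})

test_that("rank-sum p-values match exact enumeration and wilcox.test", {
  # complete separation, n1 = 3 vs n2 = 5: p = 2 * (3! 5! / 8!)
  x <- c(10, 11, 12); y <- c(1, 2, 3, 4, 5)
  expect_equal(compare_to_null(x, y),
               2 * factorial(3) * factorial(5) / factorial(8))
  # identical samples sit in the p ~ 1 region
  expect_gt(compare_to_null(c(1, 2, 3), c(1.1, 2.1, 2.9)), 0.5)
  # random no-tie cases vs full enumeration oracle (n1 + n2 <= 10)
  set.seed(51)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(compare_to_null(x, y), oracle_ranksum_exact(x, y),
                 tolerance = 1e-12)
    expect_equal(compare_to_null(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample path agrees with the normal approximation of wilcox.test
  set.seed(52)
  x <- rnorm(30); y <- rnorm(40, 0.4)
  expect_equal(compare_to_null(x, y),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # ties force the corrected approximation
  xt <- c(rep(1, 10), rep(2, 15)); yt <- c(rep(1, 12), rep(3, 13))
  expect_equal(compare_to_null(xt, yt),
               suppressWarnings(wilcox.test(xt, yt,
                                            correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("AUROC equals the brute-force pairwise U-statistic", {
  # 4-pathway toy: labels 1,1,0,0, scores .9,.4,.6,.1 -> 3 of 4 pairs win
  expect_equal(auroc_ustat(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(61)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(auroc_ustat(scores, labels),
                 oracle_auroc_pairs(scores, labels))
  }
  expect_warning(one <- auroc_ustat(1:4, c(1, 1, 1, 1)), "single-class")
  expect_true(is.na(one))
})

test_that("pathway AUROC uses drug labels and signed knockdown scores", {
  drug <- toy_enrichment(sprintf("P%02d", 1:8),
                         c(0.01, 0.02, 0.4, 0.6, 0.01, 0.7, 0.03, 0.5),
                         c(2.0, 1.5, 0.3, -0.2, -1.8, 0.1, -2.2, -0.4))
  # a knockdown identical to the drug is a perfect predictor
  perfect_up <- pathway_auroc(drug, drug, "up")
  expect_equal(perfect_up$auroc, 1)
  expect_equal(perfect_up$n_pos, 2)   # P01, P02 up-significant
  perfect_dn <- pathway_auroc(drug, drug, "down")
  expect_equal(perfect_dn$auroc, 1)
  expect_equal(perfect_dn$n_pos, 2)   # P05, P07 down-significant
  # direction=down negates scores so larger still predicts positive
  kd <- drug; kd$NES <- -drug$NES
  expect_equal(pathway_auroc(drug, kd, "down")$auroc, 0)
  expect_error(pathway_auroc(drug, toy_enrichment("ZZ", 0.5, 1), "up"),
               "no shared pathways")
})

test_that("true targets separate from the decoy null on synthetic data", {
  sim <- small_sim()
  drug <- sim$profiles[["drug"]]
  kd_fun <- function(g) sim$profiles[[paste0("KD:", g)]]
  rep <- concordance_report(NULL, drug, sim$truth$true_targets,
                            sim$truth$decoy_genes, n_null = 40,
                            seed = 2, kd_fun = kd_fun)
  expect_gt(min(rep$candidate_pcc),
            quantile(rep$null_pcc, 0.95, na.rm = TRUE))
  expect_lt(rep$ranksum_p, 0.01)
  # per-pair union basis widens the gene subset but preserves separation
  rep_u <- concordance_report(NULL, drug, sim$truth$true_targets,
                              sim$truth$decoy_genes, n_null = 40,
                              seed = 2, kd_fun = kd_fun, basis = "union")
  expect_identical(rep_u$meta$basis, "union")
  expect_false(identical(rep_u$candidate_pcc, rep$candidate_pcc))
  expect_gt(min(rep_u$candidate_pcc),
            quantile(rep_u$null_pcc, 0.95, na.rm = TRUE))
  # report serialization
  dir <- tempfile()
  write_concordance_report(rep, dir)
  expect_true(file.exists(file.path(dir, "concordance.json")))
  js <- jsonlite::read_json(file.path(dir, "concordance.json"))
  expect_equal(js$ranksum_p, rep$ranksum_p, tolerance = 1e-12)
})
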