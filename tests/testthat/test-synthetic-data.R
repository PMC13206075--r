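test_that("config validation names the offending field", {
  expect_error(simulation_config(n_genes = -5), "n_genes")
  expect_error(simulation_config(consensus_support = 9, n_datasets = 7),
               "consensus_support")
  expect_error(simulation_config(set_size_range = c(1, 10)),
               "set_size_range")
  expect_error(simulation_config(n_active_sets = 99, n_gene_sets = 10),
               "n_active_sets")
  expect_error(simulation_config(true_targets = "NOT_A_GENE"),
               "true_targets")
  expect_error(simulation_config(drug_noise_sd = -1), "drug_noise_sd")
})

test_that("identical config and seed give identical output, other seeds differ", {
  cfg <- simulation_config(n_datasets = 2, n_genes = 120,
                           n_samples_per_group = 3, n_gene_sets = 6,
                           n_active_sets = 2, consensus_support = 1,
                           set_size_range = c(5, 10), n_decoys = 10,
                           seed = 11)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(a$datasets[[1]]$counts,
                         simulate_study(cfg2)$datasets[[1]]$counts))
  # byte-identical serialized outputs as well
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_count_dataset(a$datasets[[1]], f1, g1)
  write_count_dataset(b$datasets[[1]], f2, g2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null simulation has no planted effect and recovers ~0 log2FC", {
  cfg <- simulation_config(n_datasets = 4, n_genes = 200,
                           n_samples_per_group = 8, n_gene_sets = 5,
                           n_active_sets = 0, consensus_support = 1,
                           set_size_range = c(5, 10), n_decoys = 10,
                           seed = 3)
  sim <- simulate_study(cfg)
  expect_true(all(lengths(sim$truth$de_genes) == 0))
  lfc <- rowMeans(vapply(sim$datasets, function(d) {
    differential_expression(filter_low_counts(d))$log2FoldChange
  }, numeric(cfg$n_genes)))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("planted log2FC = 2 is recovered within 0.3 on average", {
  # Monte-Carlo check against the generator's own truth at n = 20/group
  ests <- unlist(lapply(1:10, function(s) {
    cfg <- simulation_config(n_datasets = 1, n_genes = 300,
                             n_samples_per_group = 20, n_gene_sets = 6,
                             n_active_sets = 2, consensus_support = 1,
                             set_size_range = c(10, 20), de_log2fc = 2,
                             n_decoys = 10, seed = 100 + s)
    sim <- simulate_study(cfg)
    res <- differential_expression(filter_low_counts(sim$datasets[[1]]))
    planted <- names(sim$truth$de_genes[[1]])
    planted <- planted[sim$truth$de_genes[[1]] > 0]
    res$log2FoldChange[match(planted, res$gene)]
  }))
  expect_lt(abs(mean(ests) - 2), 0.3)
})

test_that("gene sets round-trip through GMT and active sets overlap DE genes", {
  sim <- small_sim()
  path <- tempfile(fileext = ".gmt")
  write_gmt(sim$gene_sets, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, identity), lapply(sim$gene_sets, identity))
  # active set members are exactly the planted DE genes: hypergeometric
  # overlap p is vanishingly small (exact tail from first principles)
  de1 <- unique(names(sim$truth$de_genes[[
    strsplit(sim$truth$active_sets$datasets[1], ";")[[1]][1]]]))
  set1 <- sim$gene_sets[[sim$truth$active_sets$set[1]]]
  N <- 400; K <- length(de1); n <- length(set1)
  k <- length(intersect(set1, de1))
  p <- sum(dhyper(k:n, K, N - K, n))
  expect_lt(p, 1e-6)
})

test_that("drug profile is the mean of target knockdowns plus bounded noise", {
  cfg <- simulation_config(n_datasets = 2, n_genes = 300,
                           n_samples_per_group = 3, n_gene_sets = 6,
                           n_active_sets = 2, consensus_support = 1,
                           set_size_range = c(5, 10), drug_noise_sd = 0,
                           n_decoys = 20, seed = 9)
  sim <- simulate_study(cfg)
  kd_mean <- Reduce(`+`, sim$truth$true_kd_profiles) /
    length(sim$truth$true_kd_profiles)
  expect_equal(sim$profiles[["drug"]], kd_mean,
               ignore_attr = TRUE)
  # single-target, zero-noise: drug identical to that target's KD profile
  cfg1 <- simulation_config(n_datasets = 2, n_genes = 300,
                            n_samples_per_group = 3, n_gene_sets = 6,
                            n_active_sets = 2, consensus_support = 1,
                            set_size_range = c(5, 10), drug_noise_sd = 0,
                            true_targets = "G000005", n_decoys = 20,
                            seed = 9)
  sim1 <- simulate_study(cfg1)
  expect_equal(sim1$profiles[["drug"]],
               sim1$profiles[["KD:G000005"]], ignore_attr = TRUE)
})

test_that("decoy knockdowns are uncorrelated with the drug profile", {
  sim <- small_sim()
  drug <- sim$profiles[["drug"]]
  pccs <- vapply(sim$truth$decoy_genes, function(g)
    cor(sim$profiles[[paste0("KD:", g)]], drug), numeric(1))
  expect_lt(abs(mean(pccs)), 0.05)
  # ...while true-target knockdowns dominate the decoys stochastically
  target_pcc <- vapply(sim$truth$true_targets, function(g)
    cor(sim$profiles[[paste0("KD:", g)]], drug), numeric(1))
  expect_gt(min(target_pcc), quantile(pccs, 0.95))
})

test_that("ground truth serializes to JSON", {
  sim <- small_sim()
  path <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- jsonlite::read_json(path)
  expect_identical(unlist(back$true_targets), sim$truth$true_targets)
})
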