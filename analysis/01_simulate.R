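#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study — seven negative-binomial count
# datasets sharing planted pathway signals, a gene-set collection, and
# knockdown/drug perturbation profiles — and write every input table.

suppressPackageStartupMessages(library(dedtarget))

outdir <- "results/01_inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 101L)   # study defaults: K = 7, 2000 genes
sim <- simulate_study(cfg)

for (ds in names(sim$datasets))
  write_count_dataset(sim$datasets[[ds]],
                      file.path(outdir, paste0(ds, "_counts.tsv")),
                      file.path(outdir, paste0(ds, "_groups.tsv")))
write_gmt(sim$gene_sets, file.path(outdir, "gene_sets.gmt"))
for (lab in names(sim$profiles)) {
  p <- sim$profiles[[lab]]
  attr(p, "label") <- lab
  write_profile(p, file.path(outdir, paste0(gsub(":", "_", lab), ".tsv")))
}
write_ground_truth(sim$truth, file.path(outdir, "ground_truth.json"))

cat(sprintf("Simulated %d datasets x %d genes (%d samples/group).\n",
            cfg$n_datasets, cfg$n_genes, 2 * cfg$n_samples_per_group))
cat(sprintf("Planted %d active sets (support %d of %d datasets), log2FC = %.1f.\n",
            cfg$n_active_sets, cfg$consensus_support, cfg$n_datasets,
            cfg$de_log2fc))
cat(sprintf("True targets: %s; %d decoy knockdowns; drug noise sd = %.2f.\n",
            paste(sim$truth$true_targets, collapse = ", "),
            length(sim$truth$decoy_genes), cfg$drug_noise_sd))
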