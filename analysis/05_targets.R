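#!/usr/bin/env Rscript
# Stage 5: target triage — intersect the predicted drug-target list with
# the core leading-edge genes to nominate key genes, then filter the
# docked targets by the binding-affinity threshold (< -6.5 kcal/mol).

suppressPackageStartupMessages(library(dedtarget))

outdir <- "results/05_targets"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

truth <- jsonlite::read_json("results/01_inputs/ground_truth.json")
true_targets <- unlist(truth$true_targets)
core <- readLines("results/04_consensus/core_genes.txt")

# synthetic predicted-target list: the true targets plus random genes,
# standing in for a reverse-docking prediction server's output
universe <- read.delim("results/01_inputs/DS01_counts.tsv",
                       stringsAsFactors = FALSE)$gene
set.seed(501)
predicted <- c(true_targets,
               sample(setdiff(universe, true_targets), 30))
writeLines(predicted, file.path(outdir, "predicted_targets.txt"))

targets <- read_target_list(file.path(outdir, "predicted_targets.txt"))
cat(sprintf("Predicted targets: %d raw, %d after harmonization\n",
            attr(targets, "n_raw"), attr(targets, "n_harmonized")))

key <- intersect_targets(targets, harmonize_symbols(core))
writeLines(key, file.path(outdir, "key_genes.txt"))
cat(sprintf("Key genes (targets ∩ core leading-edge): %d — %s\n",
            length(key), paste(key, collapse = ", ")))
cat(sprintf("True targets recovered among key genes: %d of %d\n",
            sum(toupper(true_targets) %in% key), length(true_targets)))

dock <- read_docking_table(system.file(
  "extdata", "teriflunomide_docking_affinities.tsv", package = "dedtarget"))
prio <- filter_by_affinity(dock, threshold = -6.5)
write.table(prio, file.path(outdir, "prioritized_targets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Docked targets below -6.5 kcal/mol: %s\n",
            paste(sprintf("%s (%.2f)", prio$target, prio$affinity),
                  collapse = ", ")))
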