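#!/usr/bin/env Rscript
# Stage 4: cross-dataset consensus — pathways significantly enriched with
# a consistent direction in at least half of the datasets, leading-edge
# occurrence frequencies within the contributing datasets, and core
# leading-edge genes at frequency > 0.5.

suppressPackageStartupMessages(library(dedtarget))

indir <- "results/03_gsea"
outdir <- "results/04_consensus"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

gsea_files <- list.files(indir, pattern = "_gsea\\.tsv$")
results <- lapply(gsea_files, function(f)
  read.delim(file.path(indir, f), stringsAsFactors = FALSE,
             colClasses = c(leadingEdge = "character")))
names(results) <- sub("_gsea\\.tsv$", "", gsea_files)
results <- lapply(results, function(r) {
  r$leadingEdge[is.na(r$leadingEdge)] <- ""
  r
})

cons <- consensus_pathways(results, alpha = 0.05, min_frac = 0.5)
write.table(cons, file.path(outdir, "consensus_pathways.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("K = %d datasets, support threshold = %d\n",
            length(results), ceiling(0.5 * length(results))))
cat(sprintf("%d consensus pathways (%d up, %d down)\n", nrow(cons),
            sum(cons$direction == "up"), sum(cons$direction == "down")))

freq <- leading_edge_frequency(cons, results)
write.table(freq, file.path(outdir, "core_gene_frequency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
core <- core_leading_edge_genes(freq, min_freq = 0.5)
writeLines(core, file.path(outdir, "core_genes.txt"))
cat(sprintf("%d leading-edge genes scored; %d core (frequency > 0.5)\n",
            nrow(freq), length(core)))
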