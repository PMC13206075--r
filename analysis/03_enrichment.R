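#!/usr/bin/env Rscript
# Stage 3: pre-ranked gene-set enrichment per dataset, ranking genes by
# log2 fold change and testing each set against a gene-permutation null
# (500 permutations), with leading-edge extraction.

suppressPackageStartupMessages(library(dedtarget))

indir <- "results/02_de"
outdir <- "results/03_gsea"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

collection <- read_gmt("results/01_inputs/gene_sets.gmt")
de_files <- list.files(indir, pattern = "_de\\.tsv$")
seed <- 301L
for (df in de_files) {
  ds <- sub("_de\\.tsv$", "", df)
  res <- read.delim(file.path(indir, df), stringsAsFactors = FALSE)
  ranked <- rank_genes(res)
  gsea <- preranked_gsea(ranked, collection, n_perm = 500,
                         seed = seed + match(df, de_files))
  write.table(gsea, file.path(outdir, paste0(ds, "_gsea.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d sets tested, %d significant at p < 0.05 (%d up, %d down)\n",
              ds, nrow(gsea), sum(gsea$pval < 0.05),
              sum(gsea$pval < 0.05 & gsea$direction == "up"),
              sum(gsea$pval < 0.05 & gsea$direction == "down")))
}
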